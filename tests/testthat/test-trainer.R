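test_that("the replay buffer is an exact FIFO at its stated capacity", {
  buf <- replay_buffer(100000L)
  buffer_add(buf, as.list(seq_len(100001L)))   # sentinel samples
  expect_equal(buffer_size(buf), 100000L)
  oldest <- buffer_peek(buf, 3)                # internal oldest-first view
  expect_equal(unlist(oldest), c(2L, 3L, 4L))  # sample 1 was evicted
  # small-capacity check of exact eviction order
  b2 <- replay_buffer(3L)
  buffer_add(b2, list("a", "b", "c", "d", "e"))
  expect_equal(unlist(buffer_peek(b2)), c("c", "d", "e"))
})

test_that("buffer sampling clamps, reproduces under a seed, and rejects empty", {
  buf <- replay_buffer(100L)
  buffer_add(buf, as.list(1:10))
  expect_length(buffer_sample(buf, 2024), 10L)
  set.seed(5); a <- buffer_sample(buf, 5)
  set.seed(5); b <- buffer_sample(buf, 5)
  expect_identical(a, b)
  expect_error(buffer_sample(replay_buffer(10L), 1), "empty")
})

test_that("pool sampling follows the error-balanced distribution", {
  mk <- function(n) lapply(seq_len(n), function(i) {
    list(id = paste0("r", i), seq = "GGGGAAAACCCC", native = "((((....))))")
  })
  pool <- rna_pool(mk(2))
  expect_equal(as.numeric(pool_probs(pool)), c(0.5, 0.5))     # symmetric start
  # V = (1, 1), N = (1, 2), L = (10, 10) -> P1 = e^0.1 / (e^0.1 + e^0.05)
  pool$V <- c(1, 1); pool$N <- c(1L, 2L); pool$L <- c(10L, 10L)
  expect_equal(pool_probs(pool)[[1]],
               exp(0.1) / (exp(0.1) + exp(0.05)), tolerance = 1e-12)
  expect_equal(round(pool_probs(pool)[[1]], 4), 0.5125)
  # raising V_i strictly raises P_i
  p0 <- pool_probs(pool)[[1]]
  pool_update(pool, 1L, 5L)
  pool$N[1] <- 1L                     # isolate the V effect
  expect_gt(pool_probs(pool)[[1]], p0)
  # probabilities always sum to one over random pools
  set.seed(41)
  for (k in 1:50) {
    pool <- rna_pool(mk(sample(2:6, 1)))
    pool$V <- runif(length(pool$ids), 0, 50)
    pool$N <- sample.int(20, length(pool$ids), replace = TRUE)
    expect_equal(sum(pool_probs(pool)), 1)
  }
})

test_that("advantage is the Q - V difference", {
  expect_equal(compute_advantage(3, 1), 2)
  expect_equal(compute_advantage(2, 2), 0)
  expect_lt(compute_advantage(1, 3), 0)
})

test_that("oracle-guided episodes fold the toy hairpin exactly", {
  env <- rna_env("GAAAC", secondary_structure(rbind(c(1, 5))))
  rec <- run_episode(env, make_oracle_evaluator(), search_config(16, 5, "argmax"))
  expect_equal(rec$path, rbind(c(1L, 5L)))
  expect_equal(rec$r, 0L)
  h <- gen_hairpin(4, 4)
  envh <- rna_env(h$seq, h$native)
  rech <- run_episode(envh, make_oracle_evaluator(), search_config(64, 5, "argmax"))
  expect_equal(rech$r, 0L)
  expect_lte(rech$n_steps, n_pairs(h$native) + 1L)
})

test_that("finalized samples carry the shared final reward and normalized policies", {
  h <- gen_hairpin(4, 4)
  env <- rna_env(h$seq, h$native)
  rec <- run_episode(env, make_oracle_evaluator(), search_config(32, 5, "argmax"))
  samples <- finalize_samples(rec)
  expect_length(samples, rec$n_steps)
  for (s in samples) {
    expect_equal(s$r, rec$r)               # final error shared by every step
    expect_equal(sum(s$target_policy), 1, tolerance = 1e-12)
    expect_equal(dim(s$x), c(144L, 18L))
  }
  # the value target is the per-state error: 4, 3, 2, 1 down the exact fold
  expect_equal(vapply(samples, `[[`, 1L, "target_value"),
               seq(n_pairs(h$native), by = -1L, length.out = rec$n_steps))
})

test_that("training runs log every episode and are seed-reproducible", {
  h <- gen_hairpin(2, 4)
  target <- list(id = "hp2", seq = h$seq, native = h$native)
  cfg <- train_config(episodes = 2, n_simulations = 8, batch_size = 8,
                      channels = c(2, 4, 4), workers = 1, seed = 99)
  out1 <- tempfile(); out2 <- tempfile()
  runA <- train_fold(target, cfg, out_dir = out1)
  runB <- train_fold(target, cfg, out_dir = out2)
  expect_equal(nrow(runA$episodes), 2L)
  expect_identical(runA$episodes, runB$episodes)
  expect_identical(runA$paths, runB$paths)
  expect_identical(readLines(file.path(out1, "episodes.jsonl")),
                   readLines(file.path(out2, "episodes.jsonl")))
  log <- read_episode_log(file.path(out1, "episodes.jsonl"))
  expect_equal(log$episodes$r, runA$episodes$r)
  expect_identical(log$paths, lapply(runA$paths, function(p) {
    matrix(as.integer(p), ncol = 2)
  }))
})

test_that("with an oracle evaluator every training episode reaches the native state", {
  set.seed(43)
  for (k in 1:5) {
    h <- gen_hairpin(sample(2:5, 1), sample(3:6, 1), bases = NULL)
    env <- rna_env(h$seq, h$native)
    rec <- run_episode(env, make_oracle_evaluator(), search_config(48, 5, "argmax"))
    expect_equal(rec$r, 0L)
  }
})

test_that("prediction mode is deterministic and returns a legal structure", {
  net <- policy_value_network(c(2, 4, 4), seed = 17)
  p1 <- predict_structure("GAAAC", net, n_simulations = 8)
  p2 <- predict_structure("GAAAC", net, n_simulations = 8)
  expect_identical(p1$path, p2$path)        # nonstochastic selection
  expect_equal(p1$struct$pairs, as_pairs(rbind(c(1, 5))))
  expect_equal(p1$dotbracket, "(...)")
  h <- gen_hairpin(3, 4)
  ph <- predict_structure(h$seq, net, n_simulations = 16)
  expect_silent(secondary_structure(ph$struct$pairs))   # mutually consistent
})

test_that("config round-trips through YAML", {
  cfg <- train_config(episodes = 5, n_simulations = 16, workers = 2, seed = 3)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), path)
  back <- read_train_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-6)  # YAML float precision
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(episodes = 5, bogus_key = 1), bad)
  expect_error(read_train_config(bad), "unknown config key")
})
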