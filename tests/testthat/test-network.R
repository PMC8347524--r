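make_state <- function(seq = "GAAAC", native = rbind(c(1, 5))) {
  env_reset(rna_env(seq, secondary_structure(native)))
}

test_that("forward pass honours the output contracts", {
  net <- policy_value_network(c(4, 8, 8), seed = 101)
  st <- make_state()
  out <- net_forward(net, st)
  expect_length(out$policy, 25L)          # L^2 for L = 5
  expect_equal(sum(out$policy), 1, tolerance = 1e-12)
  expect_gt(out$value, 0)                 # softplus keeps the value positive
  # determinism: same input, same output
  out2 <- net_forward(net, st)
  expect_identical(out$policy, out2$policy)
  expect_identical(out$value, out2$value)
  # the array and state forms agree
  out3 <- net_forward(net, encode_state(st))
  expect_equal(out$policy, out3$policy)
  expect_error(net_forward(net, array(0, c(17, 5, 5))), "18 x L x L")
})

test_that("one network serves different sequence lengths", {
  net <- policy_value_network(c(4, 8, 8), seed = 103)
  o5 <- net_forward(net, make_state())
  h <- gen_hairpin(4, 4)
  o12 <- net_forward(net, env_reset(rna_env(h$seq, h$native)))
  expect_length(o5$policy, 25L)
  expect_length(o12$policy, 144L)
  expect_gt(o12$value, 0)
})

test_that("batched and single forward passes agree", {
  net <- policy_value_network(c(4, 8, 8), seed = 105)
  h <- gen_hairpin(4, 4)
  env <- rna_env(h$seq, h$native)
  st1 <- env_reset(env)
  st2 <- env_step(st1, c(1, 12))$state
  batch <- net_forward(net, list(st1, st2))
  one1 <- net_forward(net, st1)
  one2 <- net_forward(net, st2)
  expect_equal(as.vector(batch$policy[1, ]), one1$policy, tolerance = 1e-12)
  expect_equal(as.vector(batch$policy[2, ]), one2$policy, tolerance = 1e-12)
  expect_equal(batch$value, c(one1$value, one2$value), tolerance = 1e-12)
})

test_that("masking zeroes illegal cells and renormalizes", {
  st <- make_state()                       # single legal action (1, 5)
  pol <- mask_and_normalize(runif(25), st$space, 5)
  expect_equal(as.numeric(pol), 1)
  expect_equal(names(pol), "1-5")
  sp <- enumerate_initial(rna_sequence("GGGGAAAACCCC"))
  uniform <- mask_and_normalize(rep(1 / 144, 144), sp, 12)
  expect_equal(as.numeric(uniform), rep(1 / 16, 16))
  # all-zero legal mass falls back to uniform
  zeros <- mask_and_normalize(numeric(144), sp, 12)
  expect_equal(as.numeric(zeros), rep(1 / 16, 16))
  # already-normalized legal mass is unchanged
  raw <- numeric(25); raw[1 + 4 * 5] <- 0.6
  sp2 <- enumerate_initial(rna_sequence("GAAAC"))
  expect_equal(as.numeric(mask_and_normalize(raw, sp2, 5)), 1)
  empty <- restrict_after(sp2, c(1, 5))
  expect_error(mask_and_normalize(raw, empty, 5), "empty action space")
})

test_that("losses hit their analytic floors", {
  net <- policy_value_network(c(4, 8, 8), seed = 107)
  st <- make_state()
  out <- net_forward(net, st)
  # perfect predictions -> zero value loss, policy loss = target entropy
  sample_perfect <- list(x = st, target_policy = out$policy,
                         target_value = out$value)
  l <- net_loss(net, list(sample_perfect))
  expect_equal(l$value_loss, 0, tolerance = 1e-12)
  entropy <- -sum(out$policy * log(out$policy))
  expect_equal(l$policy_loss, entropy, tolerance = 1e-8)
  expect_equal(l$total, l$value_loss + l$policy_loss)
  # one-hot target with all mass predicted there -> zero policy loss floor
  onehot <- numeric(25); onehot[which.max(out$policy)] <- 1
  l2 <- net_loss(net, list(list(x = st, target_policy = onehot, target_value = 1)))
  expect_gte(l2$policy_loss, 0)
  expect_error(net_loss(net, list(list(x = st, target_policy = rep(NaN, 25),
                                       target_value = 1))), "NaN")
})

test_that("a gradient step decreases the loss on a repeated sample", {
  set.seed(109)
  net <- policy_value_network(c(4, 8, 8), seed = 109)
  st <- make_state()
  target <- numeric(25); target[1 + 4 * 5] <- 1
  batch <- list(list(x = st, target_policy = target, target_value = 2))
  l0 <- net_loss(net, batch)$total
  net <- net_train_step(net, batch)
  expect_equal(attr(net, "loss")$total, l0, tolerance = 1e-10)
  l1 <- net_loss(net, batch)$total
  expect_lt(l1, l0)
})

test_that("the network memorizes five states to value error below 0.1", {
  set.seed(111)
  h <- gen_hairpin(4, 4)
  env <- rna_env(h$seq, h$native)
  st <- env_reset(env)
  states <- list(st)
  for (r in 1:4) {
    st <- env_step(st, h$native$pairs[r, ])$state
    states[[r + 1L]] <- st
  }
  states <- states[1:5]
  targets <- c(4, 3, 2, 1, 0.2)    # value head is strictly positive
  batch <- lapply(1:5, function(k) {
    list(x = states[[k]], target_policy = rep(1 / 144, 144),
         target_value = targets[k])
  })
  net <- policy_value_network(c(8, 16, 16), lr = 0.005, seed = 111)
  for (it in 1:500) {
    net <- net_train_step(net, batch)
    vals <- net_forward(net, states)$value
    if (max(abs(vals - targets)) < 0.1) break
  }
  expect_lt(max(abs(net_forward(net, states)$value - targets)), 0.1)
})

test_that("checkpoints round-trip parameters", {
  net <- policy_value_network(c(4, 8, 8), seed = 113)
  path <- tempfile(fileext = ".rds")
  net_save(net, path)
  back <- net_load(path)
  st <- make_state()
  expect_identical(net_forward(net, st), net_forward(back, st))
})
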