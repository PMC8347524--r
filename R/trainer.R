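# Self-play training loop: episode generation, FIFO replay buffer, network
# updates, and error-balanced multi-RNA curriculum sampling.

#' Training configuration
#'
#' Defaults follow the reference protocol: 1000 episodes per RNA, 2000 tree
#' searches per step, a 100,000-sample FIFO replay database, batches of 2024
#' samples, and 20 episode workers per generation round sharing one frozen
#' parameter snapshot.
#'
#' @param episodes Total self-play episodes.
#' @param n_simulations Tree searches per folding step.
#' @param batch_size Samples drawn from the replay buffer per network update
#'   (clamped to the buffer size when smaller).
#' @param updates_per_round Gradient steps per generation round; several
#'   smaller batches can stand in for one large one at equal sample
#'   throughput.
#' @param buffer_capacity FIFO replay capacity.
#' @param workers Episodes generated per round against a frozen snapshot;
#'   updates happen between rounds. `workers = 1` is bit-reproducible under
#'   a fixed seed.
#' @param channels Conv widths of the network.
#' @param lr Adam learning rate.
#' @param c Exploration constant.
#' @param action_select Training-time action choice (see [search_config()]).
#' @param root_noise,noise_alpha Dirichlet root-prior noise for self-play
#'   searches (see [search_config()]); prediction mode never uses it.
#' @param explore_frac Fraction of the episodes run with the configured
#'   (stochastic) `action_select`; the remaining episodes use deterministic
#'   `"argmax"` selection, annealing exploration away once the networks have
#'   stabilized. Ignored when `action_select` is already `"argmax"`.
#' @param stop_threshold Value-head stop threshold tau.
#' @param mode Pseudoknot mode of the environment.
#' @param seed Master seed for the whole run.
#' @param store_policies Keep per-step sparse corrected policies in the
#'   episode log.
#' @param checkpoint_every Write a checkpoint every this many episodes when
#'   an output directory is given (0 = only at the end).
#' @return Object of class `train_config`.
#' @export
train_config <- function(episodes = 1000L, n_simulations = 2000L,
                         batch_size = 2024L, updates_per_round = 1L,
                         buffer_capacity = 100000L,
                         workers = 20L, channels = DEFAULT_CHANNELS,
                         lr = 0.001, c = 5,
                         action_select = c("sample", "argmax", "score"),
                         root_noise = 0.25, noise_alpha = 1,
                         explore_frac = 2 / 3, stop_threshold = 0.5,
                         mode = c("pk_free", "pk_allowed"), seed = 1L,
                         store_policies = TRUE, checkpoint_every = 0L) {
  cfg <- list(episodes = as.integer(episodes),
              n_simulations = as.integer(n_simulations),
              batch_size = as.integer(batch_size),
              updates_per_round = as.integer(updates_per_round),
              buffer_capacity = as.integer(buffer_capacity),
              workers = as.integer(workers),
              channels = as.integer(channels), lr = lr, c = c,
              action_select = match.arg(action_select),
              root_noise = root_noise, noise_alpha = noise_alpha,
              explore_frac = explore_frac,
              stop_threshold = stop_threshold, mode = match.arg(mode),
              seed = as.integer(seed), store_policies = isTRUE(store_policies),
              checkpoint_every = as.integer(checkpoint_every))
  stopifnot(cfg$episodes >= 1L, cfg$n_simulations >= 1L, cfg$batch_size >= 1L,
            cfg$buffer_capacity >= 1L, cfg$workers >= 1L,
            cfg$explore_frac >= 0, cfg$explore_frac <= 1)
  structure(cfg, class = "train_config")
}

#' Read a training configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [train_config()]
#' defaults.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @export
read_train_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop(sprintf("unsupported config format '%s'", ext))
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  do.call(train_config, vals)
}

# ---- replay buffer -----------------------------------------------------

#' FIFO replay buffer
#'
#' A fixed-capacity queue of training samples: once full, each new sample
#' overwrites the earliest stored one. Implemented as a circular array so
#' adds are O(1).
#'
#' @param capacity Maximum number of samples (default 100,000).
#' @return Object of class `replay_buffer` (an environment, mutated in
#'   place).
#' @export
replay_buffer <- function(capacity = 100000L) {
  stopifnot(capacity >= 1L)
  buf <- new.env(parent = emptyenv())
  buf$data <- vector("list", capacity)
  buf$capacity <- as.integer(capacity)
  buf$size <- 0L
  buf$head <- 0L       # index of the most recently written slot
  class(buf) <- "replay_buffer"
  buf
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat(sprintf("Replay buffer: %d / %d samples\n", x$size, x$capacity))
  invisible(x)
}

#' @rdname replay_buffer
#' @param buf A `replay_buffer`.
#' @param samples A list of samples (or a single sample wrapped in `list()`).
#' @export
buffer_add <- function(buf, samples) {
  for (s in samples) {
    buf$head <- (buf$head %% buf$capacity) + 1L
    buf$data[[buf$head]] <- s
    if (buf$size < buf$capacity) buf$size <- buf$size + 1L
  }
  invisible(buf)
}

#' @rdname replay_buffer
#' @param k Number of samples to draw (uniform, without replacement; clamped
#'   to the buffer size when larger).
#' @export
buffer_sample <- function(buf, k) {
  if (buf$size == 0L) stop("cannot sample from an empty replay buffer")
  k <- min(as.integer(k), buf$size)
  buf$data[sample.int(buf$size, k)]
}

#' @rdname replay_buffer
#' @export
buffer_size <- function(buf) buf$size

# oldest-first view (for FIFO tests / inspection)
buffer_peek <- function(buf, k = buf$size) {
  if (buf$size == 0L) return(list())
  start <- if (buf$size < buf$capacity) 1L else (buf$head %% buf$capacity) + 1L
  idx <- ((start - 1L + seq_len(buf$size) - 1L) %% buf$capacity) + 1L
  buf$data[idx[seq_len(min(k, buf$size))]]
}

# ---- multi-RNA pool ----------------------------------------------------

#' Multi-RNA training pool
#'
#' Bookkeeping for the error-balanced curriculum: each RNA i carries its
#' cumulative episode error V_i (initialized to 1), its sampling count N_i
#' (initialized to 1) and its length L_i. Sampling probabilities are
#' `P_i = exp(V_i / (N_i * L_i)) / sum_i exp(V_i / (N_i * L_i))`, so RNAs
#' that keep folding badly, or have rarely been sampled, are drawn more
#' often.
#'
#' @param targets List of targets, each a list with `id`, `seq` and
#'   `native` (dot-bracket string or [secondary_structure()]).
#' @return Object of class `rna_pool` (an environment, mutated in place).
#' @export
rna_pool <- function(targets) {
  stopifnot(length(targets) >= 1L)
  pool <- new.env(parent = emptyenv())
  pool$ids <- vapply(targets, function(t) as.character(t$id), "")
  pool$targets <- targets
  pool$V <- rep(1, length(targets))
  pool$N <- rep(1L, length(targets))
  pool$L <- vapply(targets, function(t) seq_length(rna_sequence(t$seq)), 1L)
  class(pool) <- "rna_pool"
  pool
}

#' @export
print.rna_pool <- function(x, ...) {
  cat(sprintf("RNA pool: %d sequences (lengths %s)\n", length(x$ids),
              paste(range(x$L), collapse = "-")))
  invisible(x)
}

#' @rdname rna_pool
#' @param pool An `rna_pool`.
#' @return `pool_probs`: the current sampling distribution over the pool.
#' @export
pool_probs <- function(pool) {
  z <- exp(pool$V / (pool$N * pool$L))
  p <- z / sum(z)
  names(p) <- pool$ids
  p
}

#' @rdname rna_pool
#' @return `sample_rna`: the index of the drawn RNA.
#' @export
sample_rna <- function(pool) {
  sample.int(length(pool$ids), 1L, prob = pool_probs(pool))
}

#' @rdname rna_pool
#' @param idx Index of the RNA whose episode just finished.
#' @param r Final episode error.
#' @export
pool_update <- function(pool, idx, r) {
  pool$V[idx] <- pool$V[idx] + r
  pool$N[idx] <- pool$N[idx] + 1L
  invisible(pool)
}

#' Advantage A = Q - V (diagnostic)
#'
#' How much better taking a specific action (action value Q) is than the
#' state's baseline value V under the current policy. Kept as a training
#' diagnostic; the optimization itself fits the heads to search-corrected
#' targets.
#'
#' @param Q Action-value estimate.
#' @param V State-value estimate.
#' @export
compute_advantage <- function(Q, V) Q - V

# ---- episodes ----------------------------------------------------------

#' Run one self-play folding episode
#'
#' Starts from the open strand and repeatedly: searches with
#' [mcts_search()] (reusing the subtree of the previous step), picks an
#' action per `cfg$action_select`, and steps the environment. The episode
#' ends on a hard terminal (empty action space, exact native match, step
#' cap) or when the evaluator's value of the post-action state drops below
#' the environment's stop threshold.
#'
#' @param env An [rna_env()].
#' @param evaluator Value/policy function (network or oracle).
#' @param cfg A [search_config()].
#' @param record_states Keep the per-step state encodings (needed to build
#'   training samples; turn off for analysis-only runs).
#' @return Object of class `episode_record`: list with `steps` (per-step
#'   `x`, `v`, `policy`, `action`), `path` (pair matrix in formation
#'   order), `final` (chosen pairs), `r` (final error) and `n_steps`.
#' @export
run_episode <- function(env, evaluator, cfg = search_config(),
                        record_states = TRUE) {
  state <- env_reset(env)
  tree <- NULL
  steps <- list()
  path <- matrix(integer(0), ncol = 2)
  repeat {
    if (is_terminal_hard(state)) break
    search <- mcts_search(state, evaluator, cfg, tree)
    action <- select_action(search, cfg)
    root <- search$tree
    steps[[length(steps) + 1L]] <- list(
      x = if (record_states) encode_state_matrix(state) else NULL,
      v = root$W / max(root$N, 1L),
      d = if (env$has_native) pairs_distance(state$chosen, env$native$pairs) else NA_integer_,
      policy = search$probs,
      action = action)
    path <- rbind(path, action)
    res <- env_step(state, action)
    state <- res$state
    if (res$done) break
    tree <- advance_root(root, action, state)
    if (evaluator(state)$value < env$stop_threshold) break
  }
  r <- if (env$has_native) pairs_distance(state$chosen, env$native$pairs) else NA_integer_
  structure(list(steps = steps, path = unname(path), final = state$chosen,
                 r = r, n_steps = length(steps), L = env$L),
            class = "episode_record")
}

#' @export
print.episode_record <- function(x, ...) {
  cat(sprintf("Episode: %d steps, final error r = %d\n", x$n_steps, x$r))
  invisible(x)
}

#' Turn an episode into training samples
#'
#' Every step contributes one sample carrying the state encoding, the
#' search-corrected policy, the final episode error `r` (attached
#' identically to every step), and the value-head target. The value head is
#' trained to predict the state's own error from the native structure — the
#' quantity V stands for throughout the search — so its target is the
#' state's distance at the time of the step; the final `r` and the step's
#' search value estimate `v` travel with the sample for diagnostics.
#'
#' @param record An `episode_record` produced with `record_states = TRUE`.
#' @return List of samples (`x`, `target_policy` dense length `L^2`,
#'   `target_value`, `r`, `v`).
#' @export
finalize_samples <- function(record) {
  L <- record$L
  lapply(record$steps, function(st) {
    if (is.null(st$x)) stop("episode was recorded without states; rerun with record_states = TRUE")
    tp <- numeric(L * L)
    ij <- do.call(rbind, lapply(strsplit(names(st$policy), "-", fixed = TRUE), as.integer))
    tp[ij[, 1] + (ij[, 2] - 1L) * L] <- as.numeric(st$policy)
    list(x = st$x, target_policy = tp, target_value = st$d,
         r = record$r, v = st$v)
  })
}

# ---- the training loop -------------------------------------------------

#' Train a folding-path model by self-play
#'
#' Alternates generation rounds (`cfg$workers` episodes produced against a
#' frozen parameter snapshot, their samples merged into the FIFO replay
#' buffer) with one network update on a batch sampled from the buffer. With
#' several targets the RNA folded in each episode is drawn from the
#' error-balanced pool distribution ([pool_probs()]).
#'
#' @param targets A single target (list with `id`, `seq`, `native`) or a
#'   list of targets.
#' @param cfg A [train_config()].
#' @param net Optional network to continue training; default a fresh one.
#' @param out_dir Optional output directory: writes `config.yaml`,
#'   `episodes.jsonl` (one record per episode) and checkpoints.
#' @param verbose Print a progress line every 25 episodes.
#' @return Object of class `fold_run`: `net`, `episodes` (data.frame with
#'   episode, rna_id, r, n_steps), `paths` (list of pair matrices),
#'   `policies` (per-episode sparse step policies if stored), `pool`,
#'   `buffer`, `cfg`.
#' @export
train_fold <- function(targets, cfg = train_config(), net = NULL,
                       out_dir = NULL, verbose = FALSE) {
  if (!is.null(targets$seq)) targets <- list(targets)
  targets <- lapply(seq_along(targets), function(i) {
    t <- targets[[i]]
    if (is.null(t$id)) t$id <- paste0("rna", i)
    t
  })
  set.seed(cfg$seed)
  if (is.null(net)) net <- policy_value_network(cfg$channels, cfg$lr)
  pool <- rna_pool(targets)
  envs <- lapply(targets, function(t) {
    rna_env(t$seq, t$native, mode = cfg$mode, stop_threshold = cfg$stop_threshold)
  })
  buf <- replay_buffer(cfg$buffer_capacity)
  scfg_explore <- search_config(cfg$n_simulations, cfg$c, cfg$action_select,
                                root_noise = cfg$root_noise,
                                noise_alpha = cfg$noise_alpha)
  scfg_greedy <- search_config(cfg$n_simulations, cfg$c, "argmax",
                               root_noise = cfg$root_noise,
                               noise_alpha = cfg$noise_alpha)
  n_explore <- ceiling(cfg$explore_frac * cfg$episodes)
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
    log_con <- file(file.path(out_dir, "episodes.jsonl"), open = "w")
    on.exit(close(log_con), add = TRUE)
  }
  ep_rna <- character(cfg$episodes)
  ep_r <- integer(cfg$episodes)
  ep_steps <- integer(cfg$episodes)
  paths <- vector("list", cfg$episodes)
  policies <- if (cfg$store_policies) vector("list", cfg$episodes) else NULL
  episode <- 0L
  while (episode < cfg$episodes) {
    round_n <- min(cfg$workers, cfg$episodes - episode)
    snapshot <- make_net_evaluator(net)   # frozen parameters for this round
    round_samples <- list()
    for (w in seq_len(round_n)) {
      episode <- episode + 1L
      idx <- if (length(targets) > 1L) sample_rna(pool) else 1L
      scfg <- if (episode <= n_explore) scfg_explore else scfg_greedy
      rec <- run_episode(envs[[idx]], snapshot, scfg)
      pool_update(pool, idx, rec$r)
      round_samples <- c(round_samples, finalize_samples(rec))
      ep_rna[episode] <- pool$ids[idx]
      ep_r[episode] <- rec$r
      ep_steps[episode] <- rec$n_steps
      paths[[episode]] <- rec$path
      if (cfg$store_policies) {
        policies[[episode]] <- lapply(rec$steps, `[[`, "policy")
      }
      if (!is.null(log_con)) {
        writeLines(episode_json(pool$ids[idx], episode, rec, cfg$store_policies), log_con)
      }
      if (verbose && episode %% 25L == 0L) {
        message(sprintf("episode %d/%d (%s): r = %d after %d steps",
                        episode, cfg$episodes, pool$ids[idx], rec$r, rec$n_steps))
      }
    }
    buffer_add(buf, round_samples)
    for (u in seq_len(cfg$updates_per_round)) {
      net <- net_train_step(net, buffer_sample(buf, cfg$batch_size))
    }
    if (!is.null(out_dir) && cfg$checkpoint_every > 0L &&
        episode %% cfg$checkpoint_every == 0L) {
      net_save(net, file.path(out_dir, sprintf("checkpoint_%05d.rds", episode)))
    }
  }
  if (!is.null(out_dir)) net_save(net, file.path(out_dir, "checkpoint_final.rds"))
  structure(list(net = net,
                 episodes = data.frame(episode = seq_len(cfg$episodes),
                                       rna_id = ep_rna, r = ep_r,
                                       n_steps = ep_steps),
                 paths = paths, policies = policies, pool = pool,
                 buffer = buf, cfg = cfg),
            class = "fold_run")
}

#' @export
print.fold_run <- function(x, ...) {
  cat(sprintf("Folding run: %d episodes, final r = %d, median r (last 50) = %g\n",
              nrow(x$episodes), x$episodes$r[nrow(x$episodes)],
              stats::median(utils::tail(x$episodes$r, 50))))
  invisible(x)
}

episode_json <- function(rna_id, episode, rec, with_policies) {
  obj <- list(rna_id = rna_id, episode = episode, r = rec$r,
              n_steps = rec$n_steps,
              path = if (nrow(rec$path) > 0L) {
                lapply(seq_len(nrow(rec$path)), function(k) rec$path[k, ])
              } else list())
  if (with_policies) {
    obj$policies <- lapply(rec$steps, function(st) as.list(st$policy))
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Predict a secondary structure (deterministic mode)
#'
#' Folds a sequence with a trained network and no native reference:
#' selection is the deterministic most-visited child at every step, and the
#' episode stops when the value head signals completion (or the action
#' space empties). The resulting action sequence is the predicted fastest
#' folding path.
#'
#' @param seq RNA sequence (string or [rna_sequence()]).
#' @param net A trained [policy_value_network()].
#' @param n_simulations Searches per step.
#' @param c Exploration constant.
#' @param stop_threshold Value-head stop threshold.
#' @param mode Pseudoknot mode.
#' @return List with `struct` (predicted [secondary_structure()]), `path`
#'   (pair matrix in formation order) and `dotbracket`.
#' @export
predict_structure <- function(seq, net, n_simulations = 2000L, c = 5,
                              stop_threshold = 0.5,
                              mode = c("pk_free", "pk_allowed")) {
  mode <- match.arg(mode)
  seq <- rna_sequence(seq)
  env <- rna_env(seq, native = NULL, mode = mode,
                 stop_threshold = stop_threshold)
  evaluator <- make_net_evaluator(net)
  cfg <- search_config(n_simulations, c, action_select = "argmax")
  rec <- run_episode(env, evaluator, cfg, record_states = FALSE)
  struct <- layer_pairs(rec$final)
  list(struct = struct, path = rec$path,
       dotbracket = write_dotbracket(struct, seq_length(seq)))
}
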