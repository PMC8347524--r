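# The RNAWorld2D folding environment.
#
# An episode starts from the open strand (no pairs) and adds one base pair
# per step from the current action space. The reward is the error from the
# native state: the sum of squared element differences between the two
# strictly upper-triangular contact matrices, i.e. the symmetric-difference
# count of the two pair sets. Lower is better; the agent minimizes it.

#' Create an RNAWorld2D environment
#'
#' @param seq Target RNA (string or [rna_sequence()]).
#' @param native Native secondary structure (the target state), a
#'   [secondary_structure()] or dot-bracket string.
#' @param mode `"pk_free"` (actions keep the structure nested) or
#'   `"pk_allowed"` (crossing pairs stay selectable).
#' @param stop_threshold Value-head stop threshold tau: an episode may end
#'   once the estimated remaining error drops below it (see [is_terminal()]).
#' @param max_steps Hard cap on episode length; default `floor(L / 2)`, the
#'   maximum number of pairs a sequence of length L can form.
#' @return Object of class `rna_env`.
#' @export
rna_env <- function(seq, native, mode = c("pk_free", "pk_allowed"),
                    stop_threshold = 0.5, max_steps = NULL) {
  mode <- match.arg(mode)
  seq <- rna_sequence(seq)
  has_native <- !is.null(native)
  if (is.null(native)) native <- secondary_structure()   # prediction mode
  if (is.character(native)) native <- parse_dotbracket(native)
  stopifnot(inherits(native, "secondary_structure"))
  L <- seq_length(seq)
  if (nrow(native$pairs) > 0L) {
    if (max(native$pairs) > L) stop("native structure exceeds sequence length")
    ok <- is_legal(native$pairs[, 1], native$pairs[, 2], seq)
    if (!all(ok)) {
      bad <- native$pairs[!ok, , drop = FALSE]
      warning(sprintf(
        "native structure contains %d pair(s) outside the pairing alphabet/separation rules (e.g. (%d, %d)); kept as ground truth, legality governs actions only",
        nrow(bad), bad[1, 1], bad[1, 2]))
    }
  }
  if (is.null(max_steps)) max_steps <- L %/% 2L
  structure(list(seq = seq, native = native, has_native = has_native,
                 mode = mode, stop_threshold = stop_threshold,
                 max_steps = max_steps, L = L,
                 seq_channels = sequence_channels(seq)),
            class = "rna_env")
}

#' @export
print.rna_env <- function(x, ...) {
  cat(sprintf("RNAWorld2D: %d nt, %d native pairs, mode %s\n",
              x$L, nrow(x$native$pairs), x$mode))
  invisible(x)
}

# 16 sequence one-hot channels as an L^2 x 16 cell-major matrix
# (cell k = i + (j-1)*L; channel = 4*(code_i - 1) + code_j, order A,U,C,G)
sequence_channels <- function(seq) {
  codes <- seq_codes(seq)
  L <- seq_length(seq)
  ci <- rep(codes, times = L)       # base at row position i, cell-major
  cj <- rep(codes, each = L)        # base at column position j
  m <- matrix(0, L * L, 16L)
  m[cbind(seq_len(L * L), 4L * (ci - 1L) + cj)] <- 1
  m
}

#' Reset the environment to the open strand
#'
#' @param env An [rna_env()].
#' @return Object of class `folding_state`: the open strand with the full
#'   initial action space.
#' @export
env_reset <- function(env) {
  stopifnot(inherits(env, "rna_env"))
  structure(list(env = env,
                 chosen = as_pairs(NULL),
                 space = enumerate_initial(env$seq, env$mode),
                 step_index = 0L),
            class = "folding_state")
}

#' @export
print.folding_state <- function(x, ...) {
  cat(sprintf("Folding state: step %d, %d pairs chosen, %d actions left\n",
              x$step_index, nrow(x$chosen), n_actions(x$space)))
  invisible(x)
}

pairs_distance <- function(pa, pb) {
  ka <- pair_keys(pa); kb <- pair_keys(pb)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Take one folding step
#'
#' Adds `action` to the chosen pairs, restricts the action space, and
#' returns the new state with the current error from the native state as
#' reward. The `done` flag covers the hard terminal conditions (empty action
#' space, exact native match, step cap); the value-based stop signal is the
#' caller's job via [is_terminal()].
#'
#' @param state A `folding_state`.
#' @param action Length-2 integer vector `(i, j)`; must be in the current
#'   action space.
#' @return List with `state`, `reward`, `done`, `info`.
#' @export
env_step <- function(state, action) {
  stopifnot(inherits(state, "folding_state"))
  env <- state$env
  action <- as.integer(as_pairs(matrix(action, ncol = 2))[1, ])
  if (!space_has(state$space, action)) {
    explain_illegal(state, action)  # stops with the violated rule
  }
  state$chosen <- as_pairs(rbind(state$chosen, action))
  state$space <- restrict_after(state$space, action)
  state$step_index <- state$step_index + 1L
  reward <- if (env$has_native) pairs_distance(state$chosen, env$native$pairs) else NA_integer_
  done <- n_actions(state$space) == 0L ||
    (env$has_native && reward == 0L) ||
    state$step_index >= env$max_steps
  list(state = state, reward = reward, done = done,
       info = list(n_actions = n_actions(state$space)))
}

# diagnose why an action is not available and stop with that reason
explain_illegal <- function(state, action) {
  env <- state$env
  i <- action[1]; j <- action[2]
  L <- env$L
  if (i < 1L || j > L || i >= j) {
    stop(sprintf("illegal action (%d, %d): positions must satisfy 1 <= i < j <= %d", i, j, L))
  }
  if (j - i < MIN_PAIR_SEP) {
    stop(sprintf("illegal action (%d, %d): partners must be at least three bases apart (j - i >= %d)",
                 i, j, MIN_PAIR_SEP))
  }
  codes <- seq_codes(env$seq)
  if (!PAIR_OK[codes[i], codes[j]]) {
    stop(sprintf("illegal action (%d, %d): %s-%s is not an allowed pairing (A-U, C-G, G-U)",
                 i, j, RNA_BASES[codes[i]], RNA_BASES[codes[j]]))
  }
  occ <- c(state$chosen[, 1], state$chosen[, 2])
  if (i %in% occ || j %in% occ) {
    stop(sprintf("illegal action (%d, %d): a base already paired cannot pair again", i, j))
  }
  stop(sprintf("illegal action (%d, %d): crosses an already chosen pair (pseudoknot-free mode)", i, j))
}

#' Is this state terminal?
#'
#' A state is terminal when the action space is empty, when the chosen pairs
#' exactly match the native structure, or when the supplied value estimate
#' (the predicted remaining error) falls below the environment's stop
#' threshold tau — the value function's "stop signal".
#'
#' @param state A `folding_state`.
#' @param value_estimate Non-negative scalar from the value head or an
#'   oracle; default `Inf` checks only the hard conditions.
#' @return Logical.
#' @export
is_terminal <- function(state, value_estimate = Inf) {
  stopifnot(inherits(state, "folding_state"))
  if (n_actions(state$space) == 0L) return(TRUE)
  if (state$step_index >= state$env$max_steps) return(TRUE)
  if (state$env$has_native &&
      pairs_distance(state$chosen, state$env$native$pairs) == 0L) return(TRUE)
  value_estimate < state$env$stop_threshold
}

#' Encode a state for the network
#'
#' Builds the `18 x L x L` input tensor: channels 1-16 are the one-hot
#' sequence-pair encoding (fixed for the whole episode), channel 17 marks the
#' currently legal pairs, channel 18 the already chosen pairs.
#'
#' @param state A `folding_state`.
#' @return Numeric array of dim `c(18, L, L)`.
#' @export
encode_state <- function(state) {
  m <- encode_state_matrix(state)
  L <- state$env$L
  aperm(array(m, dim = c(L, L, 18L)), c(3L, 1L, 2L))
}

# cell-major L^2 x 18 matrix form used internally by the network
encode_state_matrix <- function(state) {
  env <- state$env
  L <- env$L
  m <- cbind(env$seq_channels, 0, 0)
  sp <- state$space$legal
  if (nrow(sp) > 0L) m[sp[, 1] + (sp[, 2] - 1L) * L, 17L] <- 1
  ch <- state$chosen
  if (nrow(ch) > 0L) m[ch[, 1] + (ch[, 2] - 1L) * L, 18L] <- 1
  m
}
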