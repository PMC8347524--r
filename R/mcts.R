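# Prior-weighted Monte Carlo tree search over pair-selection states.
#
# Each node holds V (running mean of the values backed through it, an
# estimated error to the native state, lower = better), N (visit count) and
# P (prior from the policy head). Selection descends by the score
#   -V + c * P * sqrt(N_parent) / (1 + N)
# where the exploration constant c defaults to 5. There is no rollout:
# the leaf is evaluated directly by the value function, and that value is
# backed up along the whole path. The tree is reused across steps of an
# episode by re-rooting at the chosen child.
#
# Nodes are R environments mutated in place; child statistics live in
# parallel vectors inside the parent, ordered lexicographically by (i, j)
# so every argmax tie-break is "smallest pair first" and deterministic.

#' Node selection score
#'
#' `-V + c * P * sqrt(N_parent) / (1 + N)`: exploitation is the negated
#' predicted error V, exploration is prior-weighted and decays with the
#' node's own visits.
#'
#' @param V Running value estimate (predicted error to native), >= 0.
#' @param N Node visit count.
#' @param P Prior probability from the policy head.
#' @param N_parent Parent visit count.
#' @param c Exploration constant (default 5).
#' @return Numeric score (vectorized over nodes).
#' @export
score_node <- function(V, N, P, N_parent, c = 5) {
  -V + c * P * sqrt(N_parent) / (1 + N)
}

#' Classical UCT score (reference scorer)
#'
#' `W/N + c * sqrt(ln(T)/N)`, where W counts successful outcomes through the
#' node, N its simulations and T the total simulations. Unvisited nodes
#' (`N = 0`) score `+Inf` to force exploration. Provided as the textbook
#' baseline; the search itself uses [score_node()].
#'
#' @param W Success count.
#' @param N Node simulations.
#' @param T_total Total simulations.
#' @param c Exploration constant (default 2).
#' @export
uct_score <- function(W, N, T_total, c = 2) {
  ifelse(N == 0, Inf, W / pmax(N, 1) + c * sqrt(log(T_total) / pmax(N, 1)))
}

#' Search configuration
#'
#' @param n_simulations Simulations per search call (default 2000).
#' @param c Exploration constant in [score_node()] (default 5).
#' @param action_select How the trainer picks the final action from the
#'   corrected policy: `"sample"` (draw from the visit distribution; the
#'   training default, giving varied folding paths), `"argmax"` (most
#'   visited, ties to the smallest pair; used in deterministic prediction
#'   mode) or `"score"` (argmax of [score_node()] over the root children).
#' @param root_noise Fraction of Dirichlet noise mixed into the root priors
#'   at the start of each search (0 disables). Self-play at small
#'   simulation budgets needs it to keep episodes from collapsing onto one
#'   deterministic trajectory; prediction mode runs with 0.
#' @param noise_alpha Dirichlet concentration parameter.
#' @return Object of class `search_config`.
#' @export
search_config <- function(n_simulations = 2000L, c = 5,
                          action_select = c("sample", "argmax", "score"),
                          root_noise = 0, noise_alpha = 1) {
  stopifnot(n_simulations >= 1L, c >= 0, root_noise >= 0, root_noise <= 1)
  structure(list(n_simulations = as.integer(n_simulations), c = c,
                 action_select = match.arg(action_select),
                 root_noise = root_noise, noise_alpha = noise_alpha),
            class = "search_config")
}

# fresh unexpanded node wrapping a folding state
new_node <- function(state, action = NULL) {
  node <- new.env(parent = emptyenv())
  node$state <- state
  node$action <- action
  node$terminal <- is_terminal_hard(state)
  node$expanded <- FALSE
  node$N <- 0L
  node$W <- 0
  node
}

# hard terminal conditions only (no value signal inside the tree)
is_terminal_hard <- function(state) {
  n_actions(state$space) == 0L ||
    state$step_index >= state$env$max_steps ||
    (state$env$has_native &&
       pairs_distance(state$chosen, state$env$native$pairs) == 0L)
}

#' Create a search tree rooted at a state
#'
#' @param state A `folding_state`.
#' @return A root node (environment).
#' @export
mcts_new_tree <- function(state) new_node(state)

# expand: children = legal actions, priors = masked/normalized policy head
expand_node <- function(node, evaluator) {
  st <- node$state
  ev <- evaluator(st)
  sp <- st$space$legal                       # already sorted lexicographically
  pri <- mask_and_normalize(ev$policy, st$space, st$env$L)
  node$ch_i <- sp[, 1]
  node$ch_j <- sp[, 2]
  node$ch_P <- as.numeric(pri)
  node$ch_N <- integer(nrow(sp))
  node$ch_W <- numeric(nrow(sp))
  node$ch_nodes <- vector("list", nrow(sp))
  node$expanded <- TRUE
  ev$value
}

#' Run one simulation
#'
#' One selection descent (argmax of [score_node()] over the children), one
#' expansion at the leaf (children = legal actions, priors from the policy
#' head), one value evaluation at the leaf, and one backup that increments N
#' and folds the leaf value into the running mean V of every node on the
#' path.
#'
#' @param tree Root node from [mcts_new_tree()] or a previous search.
#' @param evaluator Function `folding_state -> list(value, policy)`; see
#'   [make_net_evaluator()] and [make_oracle_evaluator()].
#' @param c Exploration constant.
#' @return The leaf value (invisibly); the tree is updated in place.
#' @export
run_simulation <- function(tree, evaluator, c = 5) {
  if (tree$terminal) return(invisible(NULL))
  node <- tree
  path <- list()                              # list of (parent, child index)
  while (node$expanded && !node$terminal) {
    # first-play urgency: children never evaluated score with the parent's
    # running mean, so fresh siblings neither dominate nor are starved
    # regardless of the scale of V
    fpu <- node$W / max(node$N, 1L)
    V <- ifelse(node$ch_N > 0L, node$ch_W / pmax(node$ch_N, 1L), fpu)
    k <- which.max(score_node(V, node$ch_N, node$ch_P, node$N, c))
    child <- node$ch_nodes[[k]]
    if (is.null(child)) {
      nxt <- env_step(node$state, c(node$ch_i[k], node$ch_j[k]))$state
      child <- new_node(nxt, c(node$ch_i[k], node$ch_j[k]))
      node$ch_nodes[[k]] <- child
    }
    path[[length(path) + 1L]] <- list(node = node, k = k)
    node <- child
  }
  value <- if (node$terminal) evaluator(node$state)$value else expand_node(node, evaluator)
  # backup
  tree$N <- tree$N + 1L
  tree$W <- tree$W + value
  for (step in path) {
    step$node$ch_N[step$k] <- step$node$ch_N[step$k] + 1L
    step$node$ch_W[step$k] <- step$node$ch_W[step$k] + value
    child <- step$node$ch_nodes[[step$k]]
    child$N <- child$N + 1L
    child$W <- child$W + value
  }
  invisible(value)
}

#' Run a full search and return the corrected policy
#'
#' Runs `cfg$n_simulations` simulations from the root (on top of any visit
#' statistics retained from a previous step via [advance_root()]) and
#' returns the root child visit counts normalized to a distribution — the
#' search-corrected policy stored in training samples.
#'
#' @param state Root `folding_state` (non-terminal).
#' @param evaluator Value/policy function, as in [run_simulation()].
#' @param cfg A [search_config()].
#' @param tree Optional tree reused from the previous step.
#' @return List with `probs` (named visit distribution over legal pairs),
#'   `stats` (data.frame: i, j, N, V, P, prob) and `tree` (the root, for
#'   reuse).
#' @export
mcts_search <- function(state, evaluator, cfg = search_config(), tree = NULL) {
  if (n_actions(state$space) == 0L) stop("cannot search from a state with an empty action space")
  if (is.null(tree)) tree <- mcts_new_tree(state)
  # root expansion is bookkeeping, not one of the counted simulations, so
  # k simulations distribute exactly k visits over the root children
  if (!tree$expanded && !tree$terminal) run_simulation(tree, evaluator, cfg$c)
  if (cfg$root_noise > 0 && tree$expanded) {
    g <- stats::rgamma(length(tree$ch_P), shape = cfg$noise_alpha)
    tree$ch_P <- (1 - cfg$root_noise) * tree$ch_P + cfg$root_noise * g / sum(g)
  }
  for (s in seq_len(cfg$n_simulations)) run_simulation(tree, evaluator, cfg$c)
  if (!tree$expanded) stop("search failed to expand the root (terminal state?)")
  N <- tree$ch_N
  probs <- if (sum(N) > 0L) N / sum(N) else rep(1 / length(N), length(N))
  names(probs) <- paste(tree$ch_i, tree$ch_j, sep = "-")
  stats <- data.frame(i = tree$ch_i, j = tree$ch_j, N = N,
                      V = ifelse(N > 0L, tree$ch_W / pmax(N, 1L), NA_real_),
                      P = tree$ch_P, prob = as.numeric(probs))
  list(probs = probs, stats = stats, tree = tree)
}

#' Pick the next action from a search result
#'
#' @param search Result of [mcts_search()].
#' @param cfg A [search_config()]; `cfg$action_select` decides between
#'   sampling from the visit distribution, the most-visited child, or the
#'   highest [score_node()] child.
#' @param c Exploration constant used when `action_select = "score"`.
#' @return Length-2 integer vector `(i, j)`.
#' @export
select_action <- function(search, cfg = search_config(), c = cfg$c) {
  tree <- search$tree
  k <- switch(cfg$action_select,
    sample = sample.int(length(search$probs), 1L, prob = search$probs),
    argmax = which.max(search$probs),
    score = {
      V <- ifelse(tree$ch_N > 0L, tree$ch_W / pmax(tree$ch_N, 1L), 0)
      which.max(score_node(V, tree$ch_N, tree$ch_P, tree$N, c))
    })
  c(tree$ch_i[k], tree$ch_j[k])
}

#' Re-root the tree after taking an action
#'
#' The subtree under the chosen child becomes the new tree, keeping its
#' visit statistics; siblings are discarded. If the action was never
#' expanded during search a fresh single-node tree is returned.
#'
#' @param tree Current root.
#' @param action Length-2 integer vector, a child of the root.
#' @param state The post-action `folding_state` (used for the fresh-tree
#'   fallback).
#' @return The new root node.
#' @export
advance_root <- function(tree, action, state = NULL) {
  if (tree$expanded) {
    k <- which(tree$ch_i == action[1] & tree$ch_j == action[2])
    if (length(k) == 1L && !is.null(tree$ch_nodes[[k]])) {
      return(tree$ch_nodes[[k]])
    }
  }
  if (is.null(state)) stop(sprintf("action (%d, %d) is not a child of the root and no state was supplied",
                                   action[1], action[2]))
  new_node(state, action)
}

# ---- evaluators --------------------------------------------------------

#' Network evaluator for the search
#'
#' Wraps a [policy_value_network()] as the `evaluator` used by
#' [run_simulation()]: the value head estimates the remaining error, the
#' policy head supplies the expansion priors.
#'
#' @param net A [policy_value_network()].
#' @return Function `folding_state -> list(value, policy)`.
#' @export
make_net_evaluator <- function(net) {
  force(net)
  function(state) {
    out <- net_forward(net, state)
    list(value = out$value, policy = out$policy)
  }
}

#' Oracle evaluator (true remaining distance)
#'
#' Replaces the network with ground truth: the value is the exact distance
#' between the current state and the native structure, the policy is uniform
#' over all cells. Used to test the search machinery independently of
#' learning.
#'
#' @return Function `folding_state -> list(value, policy)`.
#' @export
make_oracle_evaluator <- function() {
  function(state) {
    L <- state$env$L
    list(value = pairs_distance(state$chosen, state$env$native$pairs),
         policy = rep(1, L * L))
  }
}
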