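# Folding-path analysis: trie of episode trajectories, modal ("fastest")
# path extraction, near-native filtering and pair-formation order maps.
#
# Path trees key on ordered prefixes of the chosen pairs: two episodes that
# reach the same pair set in different orders occupy different branches,
# because the object of study is the order of formation.

#' Build a folding-path tree
#'
#' A trie over the ordered pair-choice prefixes of the given paths. Each
#' node carries the pair it was reached by, the number of episodes passing
#' through it (`visits`) and the number ending exactly there (`terminal`).
#'
#' @param paths List of folding paths; each path is a pair matrix (rows in
#'   formation order) or an `episode_record`.
#' @return Object of class `path_tree`: nested lists with fields `pair`,
#'   `visits`, `terminal`, `children` (named by `"i-j"`).
#' @export
build_tree <- function(paths) {
  paths <- lapply(paths, function(p) {
    if (inherits(p, "episode_record")) p$path else p
  })
  root <- list(pair = NULL, visits = 0L, terminal = 0L, children = list())
  for (p in paths) {
    root <- insert_path(root, p, 1L)
  }
  structure(root, class = "path_tree")
}

insert_path <- function(node, path, depth) {
  node$visits <- node$visits + 1L
  if (is.null(path) || nrow(path) < depth) {
    node$terminal <- node$terminal + 1L
    return(node)
  }
  key <- paste(path[depth, 1], path[depth, 2], sep = "-")
  child <- node$children[[key]]
  if (is.null(child)) {
    child <- list(pair = as.integer(path[depth, ]), visits = 0L,
                  terminal = 0L, children = list())
  }
  node$children[[key]] <- insert_path(child, path, depth + 1L)
  node
}

#' @export
print.path_tree <- function(x, ...) {
  cat(sprintf("Folding-path tree: %d episodes, %d first-step branches\n",
              x$visits, length(x$children)))
  invisible(x)
}

#' Extract the modal ("fastest") folding path
#'
#' Greedy maximum-visit descent from the root: at each node the child with
#' the most episode traversals is appended (ties broken by the
#' lexicographically smallest pair). Descent stops at a node where more
#' episodes terminate than continue through any single child, or at a leaf.
#'
#' @param tree A [build_tree()] result.
#' @return Pair matrix (rows in formation order); zero rows if the tree is
#'   empty of transitions.
#' @export
modal_path <- function(tree) {
  stopifnot(inherits(tree, "path_tree"))
  if (tree$visits == 0L) stop("cannot extract a modal path from an empty tree")
  node <- tree
  path <- matrix(integer(0), ncol = 2)
  repeat {
    if (length(node$children) == 0L) break
    pairs <- do.call(rbind, lapply(node$children, `[[`, "pair"))
    visits <- vapply(node$children, `[[`, 1L, "visits")
    ord <- order(-visits, pairs[, 1], pairs[, 2])
    best <- ord[1]
    if (node$terminal > visits[best]) break
    path <- rbind(path, pairs[best, ])
    node <- node$children[[best]]
  }
  unname(path)
}

#' Keep only paths ending near the native structure
#'
#' A path is kept when its final pair set differs from the native structure
#' by at most `max_diff` pairs. With `ignore_pseudoknots = TRUE` (the
#' default) the native pseudoknot-layer pairs are removed before comparing,
#' so a pseudoknot-free search is not penalized for pairs it cannot form.
#'
#' @param paths List of pair matrices or `episode_record`s.
#' @param native The native [secondary_structure()].
#' @param max_diff Maximum allowed symmetric-difference count (default 2).
#' @param ignore_pseudoknots Drop native layer >= 1 pairs from the
#'   comparison.
#' @return The retained subset of `paths` (same representation as given),
#'   with attribute `"distance"` holding the per-path distances.
#' @export
near_native_filter <- function(paths, native, max_diff = 2L,
                               ignore_pseudoknots = TRUE) {
  stopifnot(inherits(native, "secondary_structure"))
  ref <- native$pairs
  if (ignore_pseudoknots) ref <- ref[native$layers == 0L, , drop = FALSE]
  ends <- lapply(paths, function(p) {
    if (inherits(p, "episode_record")) p$final else as_pairs(p)
  })
  d <- vapply(ends, function(e) pairs_distance(e, ref), 1L)
  out <- paths[d <= max_diff]
  attr(out, "distance") <- d[d <= max_diff]
  out
}

#' Pair-formation order of a path
#'
#' @param path Pair matrix in formation order (or an `episode_record`).
#' @return Data frame `i`, `j`, `rank` with rank 1 = first-formed pair.
#' @export
pair_order_map <- function(path) {
  if (inherits(path, "episode_record")) path <- path$path
  path <- if (is.null(path) || length(path) == 0L) {
    matrix(integer(0), ncol = 2)
  } else if (!is.matrix(path)) matrix(as.integer(path), ncol = 2, byrow = TRUE) else path
  if (anyDuplicated(pair_keys(as_pairs(path))) ||
      anyDuplicated(paste(path[, 1], path[, 2]))) {
    stop("duplicate pair in path; not a legal folding trajectory")
  }
  data.frame(i = as.integer(path[, 1]), j = as.integer(path[, 2]),
             rank = seq_len(nrow(path)))
}

#' Aggregate pair-formation order over several paths
#'
#' Mean formation rank of each pair across the given (typically
#' near-native) paths; pairs missing from a path contribute nothing to its
#' mean. This is the aggregate behind "the darker, the earlier" order
#' colorings.
#'
#' @param paths List of pair matrices or `episode_record`s.
#' @return Data frame `i`, `j`, `mean_rank`, `n_paths`, sorted by
#'   `mean_rank`.
#' @export
aggregate_order_map <- function(paths) {
  maps <- lapply(paths, pair_order_map)
  all <- do.call(rbind, maps)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(i = integer(0), j = integer(0),
                      mean_rank = numeric(0), n_paths = integer(0)))
  }
  key <- paste(all$i, all$j, sep = "-")
  agg <- stats::aggregate(all$rank, by = list(key = key), FUN = mean)
  cnt <- table(key)
  ij <- do.call(rbind, lapply(strsplit(agg$key, "-", fixed = TRUE), as.integer))
  out <- data.frame(i = ij[, 1], j = ij[, 2], mean_rank = agg$x,
                    n_paths = as.integer(cnt[agg$key]))
  out[order(out$mean_rank, out$i, out$j), , drop = FALSE]
}

# ---- episode-log I/O ---------------------------------------------------

#' Read a trainer episode log
#'
#' @param path A JSONL file written by [train_fold()] (one JSON object per
#'   line with `rna_id`, `episode`, `r`, `path`).
#' @return List with `episodes` (data.frame) and `paths` (list of pair
#'   matrices).
#' @export
read_episode_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  paths <- lapply(recs, function(r) {
    p <- r$path
    if (is.null(p) || length(p) == 0L) return(matrix(integer(0), ncol = 2))
    if (is.list(p)) p <- do.call(rbind, p)
    matrix(as.integer(p), ncol = 2)
  })
  eps <- data.frame(
    episode = vapply(recs, function(r) as.integer(r$episode), 1L),
    rna_id = vapply(recs, function(r) as.character(r$rna_id), ""),
    r = vapply(recs, function(r) as.integer(r$r), 1L),
    n_steps = vapply(recs, function(r) as.integer(r$n_steps), 1L))
  list(episodes = eps, paths = paths)
}

#' Export a path tree as JSON
#'
#' @param tree A [build_tree()] result.
#' @param path Output file; when NULL the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Write an order map as TSV
#'
#' Columns `i`, `j`, `rank` (or `mean_rank`), ready for plotting.
#'
#' @param map A [pair_order_map()] or [aggregate_order_map()] data frame.
#' @param path Output file.
#' @export
write_order_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
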