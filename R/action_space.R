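# Legality rules for base pairs and action-space bookkeeping.
#
# The action space is the set of base pairs that can still be added to the
# growing structure. Legality is purely sequence-based: Watson-Crick (A-U,
# C-G) or wobble (G-U) complementarity, plus a minimum separation of at
# least three unpaired bases between the partners (j - i >= 4). The native
# structure is never consulted.

# unordered complementarity lookup, codes 1..4 = A,U,C,G
PAIR_OK <- matrix(FALSE, 4, 4)
PAIR_OK[1, 2] <- PAIR_OK[2, 1] <- TRUE  # A-U
PAIR_OK[3, 4] <- PAIR_OK[4, 3] <- TRUE  # C-G
PAIR_OK[4, 2] <- PAIR_OK[2, 4] <- TRUE  # G-U wobble

MIN_PAIR_SEP <- 4L  # j - i >= 4, i.e. >= 3 intervening bases

#' Can two bases pair?
#'
#' Allowed pairings are the standard A-U and C-G plus the G-U wobble pair.
#'
#' @param b1,b2 Single characters in `A/U/C/G` (vectorized).
#' @return Logical.
#' @examples
#' can_pair("G", "U")  # TRUE (wobble)
#' can_pair("A", "G")  # FALSE
#' @export
can_pair <- function(b1, b2) {
  c1 <- match(toupper(b1), RNA_BASES)
  c2 <- match(toupper(b2), RNA_BASES)
  if (anyNA(c1) || anyNA(c2)) stop("bases must be one of A/U/C/G")
  PAIR_OK[cbind(c1, c2)]
}

#' Is the pair (i, j) legal for this sequence?
#'
#' Legal means complementary under [can_pair()] and separated by at least
#' three bases along the chain (`j - i >= 4`).
#'
#' @param i,j 1-based positions with `i < j` (vectorized).
#' @param seq An [rna_sequence()].
#' @return Logical.
#' @export
is_legal <- function(i, j, seq) {
  seq <- rna_sequence(seq)
  codes <- seq_codes(seq)
  L <- seq_length(seq)
  stopifnot(all(i >= 1L), all(j <= L), all(i < j))
  (j - i >= MIN_PAIR_SEP) & PAIR_OK[cbind(codes[i], codes[j])]
}

#' Enumerate the initial action space
#'
#' All legal pairs of a sequence, before any pair is chosen. In both
#' pseudoknot modes this is the same set; the modes differ only in how the
#' space shrinks after selections ([restrict_after()]).
#'
#' @param seq An [rna_sequence()].
#' @param mode `"pk_free"` (nested structures only) or `"pk_allowed"`.
#' @return Object of class `action_space`: list with `legal` (sorted pair
#'   matrix) and `mode`.
#' @export
enumerate_initial <- function(seq, mode = c("pk_free", "pk_allowed")) {
  mode <- match.arg(mode)
  seq <- rna_sequence(seq)
  codes <- seq_codes(seq)
  L <- seq_length(seq)
  if (L < 1L + MIN_PAIR_SEP) {
    return(new_action_space(as_pairs(NULL), mode))
  }
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= MIN_PAIR_SEP, , drop = FALSE]
  ok <- PAIR_OK[cbind(codes[idx[, 1]], codes[idx[, 2]])]
  new_action_space(as_pairs(idx[ok, , drop = FALSE]), mode)
}

new_action_space <- function(pairs, mode) {
  structure(list(legal = pairs, mode = mode), class = "action_space")
}

#' @export
print.action_space <- function(x, ...) {
  cat(sprintf("Action space (%s): %d legal pairs\n", x$mode, nrow(x$legal)))
  invisible(x)
}

#' Number of legal actions
#' @param space An `action_space`.
#' @export
n_actions <- function(space) nrow(space$legal)

#' Restrict the action space after choosing a pair
#'
#' Removes every pair sharing a position with the chosen pair (a base can
#' pair only once). In pseudoknot-free mode the pairs crossing the chosen
#' pair are removed as well, leaving the four regions that can coexist with
#' a nested `(i, j)`: both partners before `i`, both after `j`, both strictly
#' inside, or the new pair enclosing `(i, j)`. In pseudoknot-allowed mode
#' crossing pairs are retained.
#'
#' @param space An `action_space`.
#' @param chosen Length-2 integer vector or 1-row pair matrix; must be a
#'   member of `space`.
#' @return The restricted `action_space` (always strictly smaller).
#' @export
restrict_after <- function(space, chosen) {
  stopifnot(inherits(space, "action_space"))
  chosen <- as.integer(as_pairs(matrix(chosen, ncol = 2))[1, ])
  i <- chosen[1]; j <- chosen[2]
  p <- space$legal
  hit <- which(p[, 1] == i & p[, 2] == j)
  if (length(hit) == 0L) stop(sprintf("chosen pair (%d, %d) is not in the action space", i, j))
  shares <- p[, 1] == i | p[, 1] == j | p[, 2] == i | p[, 2] == j
  keep <- !shares
  if (space$mode == "pk_free") {
    crosses <- (i < p[, 1] & p[, 1] < j & j < p[, 2]) |
               (p[, 1] < i & i < p[, 2] & p[, 2] < j)
    keep <- keep & !crosses
  }
  new_action_space(p[keep, , drop = FALSE], space$mode)
}

# membership test used by the environment
space_has <- function(space, pair) {
  p <- space$legal
  any(p[, 1] == pair[1] & p[, 2] == pair[2])
}
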