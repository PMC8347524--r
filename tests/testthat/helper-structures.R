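# Shared generators and independent oracles used across the suite.

# random nested (layer-0) structure over length L: recursive interval split
random_nested_structure <- function(L, p_pair = 0.6) {
  pairs <- matrix(integer(0), ncol = 2)
  recurse <- function(lo, hi) {
    while (lo < hi) {
      if (hi - lo >= 4L && stats::runif(1) < p_pair) {
        cand <- seq(lo + 4L, hi)
        j <- cand[sample.int(length(cand), 1L)]
        pairs <<- rbind(pairs, c(lo, j))
        recurse(lo + 1L, j - 1L)
        lo <- j + 1L
      } else {
        lo <- lo + 1L
      }
    }
  }
  recurse(1L, L)
  secondary_structure(pairs)
}

random_rna <- function(L) {
  rna_sequence(paste(sample(c("A", "U", "C", "G"), L, replace = TRUE), collapse = ""))
}

# independent brute-force legality oracle: explicit double loop, no reuse of
# the package's vectorized enumeration
brute_force_space <- function(seq) {
  seq <- rna_sequence(seq)
  chars <- strsplit(unclass(seq), "")[[1]]
  ok <- list(c("A", "U"), c("C", "G"), c("G", "U"))
  pairs <- matrix(integer(0), ncol = 2)
  L <- length(chars)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j - i < 4) next
      comp <- FALSE
      for (o in ok) {
        if ((chars[i] == o[1] && chars[j] == o[2]) ||
            (chars[i] == o[2] && chars[j] == o[1])) comp <- TRUE
      }
      if (comp) pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs
}

# brute-force restriction oracle: re-enumerate, then drop conflicts with the
# chosen set one rule at a time
brute_force_restrict <- function(seq, chosen, pk_free = TRUE) {
  pairs <- brute_force_space(seq)
  keep <- rep(TRUE, nrow(pairs))
  for (r in seq_len(nrow(chosen))) {
    ci <- chosen[r, 1]; cj <- chosen[r, 2]
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      if (a %in% c(ci, cj) || b %in% c(ci, cj)) keep[k] <- FALSE
      if (pk_free && ((ci < a && a < cj && cj < b) || (a < ci && ci < b && b < cj))) {
        keep[k] <- FALSE
      }
    }
  }
  pairs[keep, , drop = FALSE]
}

pair_in <- function(pairs, ref) {
  paste(pairs[, 1], pairs[, 2]) %in% paste(ref[, 1], ref[, 2])
}

expect_same_pairs <- function(a, b) {
  fmt <- function(m) sort(paste(m[, 1], m[, 2], sep = "-"))
  expect_identical(fmt(a), fmt(b))
}

# tiny state with exactly three legal actions (1,7), (2,7), (3,7)
toy_three_action_env <- function() {
  rna_env("GGGAAAC", secondary_structure(rbind(c(2, 7))))
}

# evaluator scoring 0 once the designated pair is chosen, 5 otherwise
toy_oracle <- function(good = c(2L, 7L), bad_value = 5) {
  function(state) {
    hit <- nrow(state$chosen) > 0L &&
      any(state$chosen[, 1] == good[1] & state$chosen[, 2] == good[2])
    list(value = if (hit) 0 else bad_value,
         policy = rep(1, state$env$L^2))
  }
}
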