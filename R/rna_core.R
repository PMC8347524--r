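# Core sequence/structure representations and format I/O.
#
# Coordinate convention used everywhere: positions are 1-based and inclusive,
# pairs are stored as (i, j) with i < j, and contact matrices are strictly
# upper-triangular so that the squared-error distance between two contact
# matrices equals the symmetric difference of the two pair sets.

RNA_BASES <- c("A", "U", "C", "G")

#' Construct an RNA sequence
#'
#' Normalizes the input (uppercase, `T` mapped to `U`, whitespace stripped)
#' and validates it against the alphabet `A/U/C/G`.
#'
#' @param x A single string, or a character vector of single bases.
#' @return An object of class `rna_sequence`: a character scalar with
#'   attributes `bases` (integer codes 1..4 for A,U,C,G) and `L` (length).
#' @examples
#' s <- rna_sequence("gaaac")
#' seq_length(s)
#' @export
rna_sequence <- function(x) {
  if (inherits(x, "rna_sequence")) return(x)
  stopifnot(is.character(x), length(x) >= 1)
  x <- paste(x, collapse = "")
  x <- toupper(gsub("[[:space:]]", "", x))
  x <- gsub("T", "U", x, fixed = TRUE)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty RNA sequence")
  codes <- match(chars, RNA_BASES)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("invalid RNA character '%s' at position %d (alphabet is A/U/C/G)",
                 chars[bad], bad))
  }
  structure(x, bases = codes, L = length(chars), class = "rna_sequence")
}

#' @rdname rna_sequence
#' @param seq An `rna_sequence`.
#' @export
seq_length <- function(seq) attr(rna_sequence(seq), "L")

#' @rdname rna_sequence
#' @export
seq_codes <- function(seq) attr(rna_sequence(seq), "bases")

#' @export
as.character.rna_sequence <- function(x, ...) {
  attributes(x) <- NULL
  x
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("RNA sequence (%d nt): %s\n", attr(x, "L"), unclass(x)))
  invisible(x)
}

# ---- pairs -------------------------------------------------------------

#' Canonicalize a base-pair matrix
#'
#' Base-pair sets are stored as integer matrices with columns `i` and `j`,
#' one row per pair, `i < j`, rows sorted lexicographically.
#'
#' @param pairs A two-column matrix (or data.frame), or NULL/empty for no pairs.
#' @return An integer matrix with columns `i`, `j`, zero or more rows.
#' @export
as_pairs <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      (!is.matrix(pairs) && length(pairs) == 0L)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2, byrow = TRUE)
  storage.mode(pairs) <- "integer"
  stopifnot(ncol(pairs) == 2)
  swap <- pairs[, 1] > pairs[, 2]
  if (any(swap)) pairs[swap, ] <- pairs[swap, 2:1]
  if (any(pairs[, 1] == pairs[, 2])) stop("a base cannot pair with itself")
  ord <- order(pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  paste(pairs[, 1], pairs[, 2], sep = "-")
}

#' Construct a secondary structure
#'
#' A secondary structure is a set of base pairs with a bracket-layer index per
#' pair: layer 0 holds the nested (round-bracket) pairs, layers >= 1 hold
#' pseudoknot pairs. No position may occur in two pairs, and layer-0 pairs
#' must be mutually non-crossing.
#'
#' @param pairs Pair matrix (see [as_pairs()]).
#' @param layers Integer vector, one layer index per pair (default all 0).
#' @return Object of class `secondary_structure` with elements `pairs`
#'   (sorted pair matrix) and `layers` (aligned integer vector).
#' @export
secondary_structure <- function(pairs = NULL, layers = NULL) {
  p <- as_pairs(pairs)
  if (is.null(layers)) {
    layers <- rep(0L, nrow(p))
  } else {
    stopifnot(length(layers) == nrow(p))
    # re-align layers with the sorted pair order
    if (nrow(p) > 0L) layers <- as.integer(layers)[order_index(pairs)]
  }
  occ <- c(p[, 1], p[, 2])
  if (anyDuplicated(occ)) {
    stop(sprintf("position %d occurs in more than one pair", occ[duplicated(occ)][1]))
  }
  l0 <- p[layers == 0L, , drop = FALSE]
  if (any_crossing(l0)) stop("layer-0 pairs must be non-crossing (nested)")
  structure(list(pairs = p, layers = as.integer(layers)),
            class = "secondary_structure")
}

# permutation that as_pairs() applies, so layer vectors can follow it
order_index <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2, byrow = TRUE)
  if (nrow(pairs) == 0L) return(integer(0))
  swap <- pairs[, 1] > pairs[, 2]
  if (any(swap)) pairs[swap, ] <- pairs[swap, 2:1]
  order(pairs[, 1], pairs[, 2])
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("Secondary structure: %d pairs (%d pseudoknot)\n",
              nrow(x$pairs), sum(x$layers > 0L)))
  invisible(x)
}

#' Number of pairs in a structure
#' @param struct A `secondary_structure`.
#' @export
n_pairs <- function(struct) nrow(struct$pairs)

# TRUE if any two pairs in the matrix cross: i < a < j < b
any_crossing <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  for (k in seq_len(n - 1L)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    rest <- pairs[(k + 1L):n, , drop = FALSE]
    if (any((i < rest[, 1] & rest[, 1] < j & j < rest[, 2]) |
            (rest[, 1] < i & i < rest[, 2] & rest[, 2] < j))) {
      return(TRUE)
    }
  }
  FALSE
}

# ---- dot-bracket -------------------------------------------------------

BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Parse dot-bracket notation
#'
#' Each bracket alphabet `()`, `[]`, `{}`, `<>` is matched with its own stack;
#' round brackets are layer 0 (nested pairs) and the others are pseudoknot
#' layers 1..3. Spaces are stripped before parsing; dots mark unpaired
#' positions.
#'
#' @param text Dot-bracket string.
#' @return A `secondary_structure`; its length context is `nchar(text)` after
#'   space stripping (attribute `L`).
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("[[:space:]]", "", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stacks <- rep(list(integer(0)), 4L)
  pairs <- matrix(integer(0), ncol = 2)
  layers <- integer(0)
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch == ".") next
    lo <- match(ch, BRACKET_OPEN)
    lc <- match(ch, BRACKET_CLOSE)
    if (!is.na(lo)) {
      stacks[[lo]] <- c(stacks[[lo]], pos)
    } else if (!is.na(lc)) {
      if (length(stacks[[lc]]) == 0L) {
        stop(sprintf("unbalanced dot-bracket: unmatched '%s' (layer %d) at position %d",
                     ch, lc - 1L, pos))
      }
      i <- stacks[[lc]][length(stacks[[lc]])]
      stacks[[lc]] <- stacks[[lc]][-length(stacks[[lc]])]
      pairs <- rbind(pairs, c(i, pos))
      layers <- c(layers, lc - 1L)
    } else {
      stop(sprintf("invalid dot-bracket character '%s' at position %d", ch, pos))
    }
  }
  for (l in 1:4) {
    if (length(stacks[[l]]) > 0L) {
      stop(sprintf("unbalanced dot-bracket: unmatched '%s' (layer %d) at position %d",
                   BRACKET_OPEN[l], l - 1L, stacks[[l]][1]))
    }
  }
  out <- secondary_structure(pairs, layers)
  attr(out, "L") <- length(chars)
  out
}

#' Write dot-bracket notation
#'
#' Inverse of [parse_dotbracket()]: layer-0 pairs become round brackets,
#' pseudoknot layers 1..3 use `[]`, `{}`, `<>`.
#'
#' @param struct A `secondary_structure`.
#' @param L Sequence length (number of characters to emit).
#' @return Dot-bracket string of length `L`.
#' @export
write_dotbracket <- function(struct, L) {
  stopifnot(inherits(struct, "secondary_structure"))
  p <- struct$pairs
  if (nrow(p) > 0L && max(p) > L) stop("pair position exceeds sequence length L")
  if (any(struct$layers > 3L)) {
    stop("structure uses more pseudoknot layers than available bracket alphabets (4)")
  }
  chars <- rep(".", L)
  if (nrow(p) > 0L) {
    chars[p[, 1]] <- BRACKET_OPEN[struct$layers + 1L]
    chars[p[, 2]] <- BRACKET_CLOSE[struct$layers + 1L]
  }
  paste(chars, collapse = "")
}

# ---- contact matrices and distance ------------------------------------

#' Contact matrix of a structure
#'
#' @param struct A `secondary_structure`.
#' @param L Sequence length.
#' @return `L x L` binary matrix, strictly upper triangular: entry `(i, j)`
#'   is 1 iff pair `(i, j)` is in the structure.
#' @export
pairs_to_matrix <- function(struct, L) {
  p <- struct$pairs
  if (nrow(p) > 0L && max(p) > L) stop("pair position exceeds sequence length L")
  m <- matrix(0L, L, L)
  if (nrow(p) > 0L) m[p] <- 1L
  m
}

#' Distance between two secondary-structure states
#'
#' The sum of squared element differences of the two strictly upper-triangular
#' contact matrices. Because entries are 0/1 this equals the cardinality of
#' the symmetric difference of the two pair sets; it is the episode reward
#' (error from the native state), positive and to be minimized.
#'
#' @param a,b `secondary_structure` objects over the same sequence length.
#' @param L Optional length check: if both carry an `L` attribute they must
#'   agree.
#' @return Non-negative integer.
#' @export
structure_distance <- function(a, b, L = NULL) {
  La <- attr(a, "L"); Lb <- attr(b, "L")
  if (!is.null(La) && !is.null(Lb) && La != Lb) {
    stop(sprintf("structures defined over different lengths (%d vs %d)", La, Lb))
  }
  ka <- pair_keys(a$pairs)
  kb <- pair_keys(b$pairs)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# ---- file formats ------------------------------------------------------

#' Read a structure file
#'
#' Supports three plain-text formats: `dbn` (line 1 `>name`, line 2 sequence,
#' line 3 dot-bracket), `bpseq` (`i base j` rows, `j = 0` for unpaired) and
#' `ct` (header line with length, then 6-column rows where column 5 is the
#' partner, 0 if unpaired). All positions are 1-based.
#'
#' @param path File path.
#' @param format One of `"dbn"`, `"bpseq"`, `"ct"`; default guessed from the
#'   file extension.
#' @return List with elements `name`, `seq` (`rna_sequence`) and `struct`
#'   (`secondary_structure`).
#' @export
read_structure_file <- function(path, format = c("auto", "dbn", "bpseq", "ct")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, dbn = "dbn", bpseq = "bpseq", ct = "ct",
                     stop(sprintf("cannot guess structure format from extension '%s'", ext)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  switch(format,
    dbn = read_dbn_lines(lines),
    bpseq = read_bpseq_lines(lines),
    ct = read_ct_lines(lines))
}

read_dbn_lines <- function(lines) {
  name <- if (startsWith(lines[1], ">")) sub("^>\\s*", "", lines[1]) else ""
  off <- if (startsWith(lines[1], ">")) 1L else 0L
  seq <- rna_sequence(lines[off + 1L])
  struct <- parse_dotbracket(lines[off + 2L])
  if (attr(struct, "L") != seq_length(seq)) {
    stop(sprintf("dbn sequence length (%d) and structure length (%d) disagree",
                 seq_length(seq), attr(struct, "L")))
  }
  list(name = name, seq = seq, struct = struct)
}

read_bpseq_lines <- function(lines) {
  lines <- lines[!grepl("^#", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(tok) != 3L)) stop("bpseq rows must have exactly 3 columns: i base j")
  i <- as.integer(vapply(tok, `[`, "", 1L))
  base <- vapply(tok, `[`, "", 2L)
  j <- as.integer(vapply(tok, `[`, "", 3L))
  collect_partner_rows(i, base, j, "bpseq")
}

read_ct_lines <- function(lines) {
  # header: "<L> <title...>"; rows: idx base prev next partner idx2
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  rows <- lines[-1]
  if (length(rows) != n) {
    stop(sprintf("CT header declares %d rows but %d present", n, length(rows)))
  }
  tok <- strsplit(trimws(rows), "\\s+")
  if (any(lengths(tok) < 6L)) stop("CT rows must have at least 6 columns")
  i <- as.integer(vapply(tok, `[`, "", 1L))
  base <- vapply(tok, `[`, "", 2L)
  j <- as.integer(vapply(tok, `[`, "", 5L))
  out <- collect_partner_rows(i, base, j, "CT")
  out$name <- paste(strsplit(trimws(lines[1]), "\\s+")[[1]][-1], collapse = " ")
  out
}

# shared bpseq/CT logic: per-position partner column -> pair set
collect_partner_rows <- function(i, base, j, what) {
  if (!identical(i, seq_along(i))) stop(sprintf("%s positions must be 1..L in order", what))
  L <- length(i)
  paired <- which(j > 0L)
  for (k in paired) {
    if (j[k] > L) stop(sprintf("%s partner %d out of range at position %d", what, j[k], k))
    if (j[j[k]] != k) {
      stop(sprintf("%s rows are not reciprocal: position %d claims partner %d but %d claims %d",
                   what, k, j[k], j[k], j[j[k]]))
    }
  }
  keep <- paired[i[paired] < j[paired]]
  pairs <- cbind(i = i[keep], j = j[keep])
  # pseudoknot pairs get layered greedily: a pair crossing any already-placed
  # pair in its layer is pushed to the next layer
  struct <- layer_pairs(pairs)
  attr(struct, "L") <- L
  list(name = "", seq = rna_sequence(paste(base, collapse = "")), struct = struct)
}

#' Assign bracket layers to an arbitrary pair set
#'
#' Greedy first-fit: pairs are taken in order of increasing `i` and each is
#' placed in the lowest layer where it crosses nothing already placed.
#'
#' @param pairs Pair matrix.
#' @return A `secondary_structure` with the computed layer indices.
#' @export
layer_pairs <- function(pairs) {
  p <- as_pairs(pairs)
  n <- nrow(p)
  layers <- integer(n)
  if (n > 1L) {
    for (k in 2:n) {
      lay <- 0L
      repeat {
        prev <- which(layers[1:(k - 1L)] == lay)
        crosses <- FALSE
        if (length(prev) > 0L) {
          a <- p[prev, 1]; b <- p[prev, 2]
          i <- p[k, 1]; j <- p[k, 2]
          crosses <- any((a < i & i < b & b < j) | (i < a & a < j & j < b))
        }
        if (!crosses) break
        lay <- lay + 1L
      }
      layers[k] <- lay
    }
  }
  secondary_structure(p, layers)
}

#' Write a structure file
#'
#' @param x List with `name`, `seq`, `struct` (as returned by
#'   [read_structure_file()]).
#' @param path Output path.
#' @param format `"dbn"`, `"bpseq"` or `"ct"`.
#' @export
write_structure_file <- function(x, path, format = c("dbn", "bpseq", "ct")) {
  format <- match.arg(format)
  seq <- rna_sequence(x$seq)
  L <- seq_length(seq)
  chars <- strsplit(unclass(seq), "")[[1]]
  partner <- integer(L)
  p <- x$struct$pairs
  if (nrow(p) > 0L) {
    partner[p[, 1]] <- p[, 2]
    partner[p[, 2]] <- p[, 1]
  }
  name <- if (is.null(x$name) || !nzchar(x$name)) "rna" else x$name
  lines <- switch(format,
    dbn = c(paste0(">", name), unclass(seq), write_dotbracket(x$struct, L)),
    bpseq = sprintf("%d %s %d", seq_len(L), chars, partner),
    ct = c(sprintf("%d %s", L, name),
           sprintf("%d %s %d %d %d %d", seq_len(L), chars, seq_len(L) - 1L,
                   c(seq_len(L - 1L) + 1L, 0L), partner, seq_len(L))))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named list of `rna_sequence` objects (T is normalized to U).
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- lapply(recs, function(r) rna_sequence(as.character(r)))
  names(out) <- names(recs)
  out
}
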