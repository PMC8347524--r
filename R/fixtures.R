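# Curated benchmark RNAs (sequences and native structures as printed in
# their sources, stored verbatim) plus a synthetic hairpin generator.
#
# Where a printed dot-bracket or sequence is internally inconsistent the
# fixture keeps the verbatim strings, flags the problem in `notes`, and the
# explicit curated pair list is authoritative; tests run against the pair
# lists.

FIXTURES <- list(
  hairpin30 = list(
    id = "hairpin30",
    description = "30-nt three-way junction RNA (bulge at C4)",
    sequence = "AAGCGGAACGAAACGUUGCUUUUGCGCCCU",
    dotbracket = ".((.((.(((...)))(((....)))))))",
    pairs = rbind(c(2, 30), c(3, 29), c(5, 28), c(6, 27), c(8, 16), c(9, 15),
                  c(10, 14), c(17, 26), c(18, 25), c(19, 24)),
    pk_free = TRUE,
    notes = "dot-bracket and pair list are consistent"),
  PDB_00312 = list(
    id = "PDB_00312",
    description = "30-nt hairpin with an internal loop",
    sequence = "GGCAGAGUCCUUCGGGACAUUGCACCUGCC",
    dotbracket = "(((((.((((....)))).......)))))",
    pairs = rbind(c(1, 30), c(2, 29), c(3, 28), c(4, 27), c(5, 26), c(7, 18),
                  c(8, 17), c(9, 16), c(10, 15)),
    pk_free = TRUE,
    notes = "dot-bracket and pair list are consistent"),
  PDB_01136 = list(
    id = "PDB_01136",
    description = "two bulged hairpins (bulges A4 and A19) joined by an open two-way loop",
    sequence = "AUGAGGAUUACCCAUAUGAGGAUUACCCAU",
    dotbracket = ".((.((....))))..((.((....)))).",
    pairs = rbind(c(2, 14), c(3, 13), c(5, 12), c(6, 11), c(17, 29), c(18, 28),
                  c(20, 27), c(21, 26)),
    pk_free = TRUE,
    notes = "dot-bracket and pair list are consistent"),
  PDB_00972 = list(
    id = "PDB_00972",
    description = "two stems side by side; 6 native pairs",
    sequence_printed = "CAUGAGGGAUUACCCAUGUGAGGAUUACCCA",
    sequence = "CAUGAGGAUUACCCAUGUGAGGAUUACCCA",
    dotbracket = "(((((.........))))((.. .......))",
    pairs = rbind(c(1, 17), c(2, 16), c(3, 15), c(4, 14), c(18, 30), c(19, 29)),
    pk_free = TRUE,
    notes = paste("printed sequence has 31 characters although the stated length is 30,",
                  "and the printed dot-bracket (stray space included) is unbalanced;",
                  "the explicit 6-pair list is authoritative. The curated 30-nt sequence",
                  "(synthetic reconstruction) drops one G from the GGG run at position 6-8,",
                  "the unique single-character deletion class under which all six printed",
                  "pairs become complementary")),
  `1Y26` = list(
    id = "1Y26",
    description = "adenine riboswitch aptamer; native structure carries 3 pseudoknot pairs",
    sequence_printed = "CGCUUCAUAUAUAAUCCUAAUGAUAUGGUUUGGGAGUUUCUACCAAGAGCCUUAAACUCUUGAUUAUGAAGUG",
    sequence = "CGCUUCAUAUAAUCCUAAUGAUAUGGUUUGGGAGUUUCUACCAAGAGCCUUAAACUCUUGAUUAUGAAGUG",
    dotbracket = "((((((((((..((((((......[[.))))))[.....)]((((((]].....))))))..)))))))))",
    pairs = NULL,   # derived from the dot-bracket (22 nested + 3 pseudoknot pairs)
    pk_free = FALSE,
    notes = paste("printed sequence has 73 characters although the stated length is 71;",
                  "the 71-char dot-bracket is stored verbatim and parses cleanly, so the",
                  "pair list is derived from it. The curated 71-nt sequence (synthetic",
                  "reconstruction) removes the duplicated AU at positions 11-12, after",
                  "which all 25 pairs of the dot-bracket are complementary")),
  bpRNA_RFAM_25409 = list(
    id = "bpRNA_RFAM_25409",
    description = "38-nt test-set hairpin",
    sequence = "AUUCAAAUAACCAAAAUCCUCGGAAGGGGAUUAAAACG",
    dotbracket = "..............(((((((....))))))))......",
    structure_editorialized = "..............(((((((....)))))))......",
    pairs = NULL,   # derived from the editorialized structure (7 pairs)
    pk_free = TRUE,
    notes = paste("printed dot-bracket has 39 characters (7 opening vs 8 closing round",
                  "brackets) against a 38-character sequence; an editorialized 38-char,",
                  "7-pair structure is stored alongside the verbatim string")))

#' Fetch a benchmark fixture
#'
#' Returns the verbatim printed sequence and dot-bracket of one of the
#' curated benchmark RNAs together with a machine-checked native pair list
#' (and, where the printed strings are inconsistent, a note saying which
#' part is authoritative).
#'
#' @param id Fixture name; see [fixture_ids()] for the available set.
#' @return List with `id`, `description`, `sequence`, `dotbracket`,
#'   `native` (a [secondary_structure()]), `pk_free` (TRUE when the native
#'   structure is pseudoknot-free and hence fully reachable in `pk_free`
#'   mode) and `notes`.
#' @export
get_fixture <- function(id) {
  fx <- FIXTURES[[id]]
  if (is.null(fx)) {
    stop(sprintf("unknown fixture '%s' (available: %s)", id,
                 paste(names(FIXTURES), collapse = ", ")))
  }
  native <- if (!is.null(fx$pairs)) {
    layer_pairs(fx$pairs)
  } else if (!is.null(fx$structure_editorialized)) {
    parse_dotbracket(fx$structure_editorialized)
  } else {
    parse_dotbracket(fx$dotbracket)
  }
  list(id = fx$id, description = fx$description, sequence = fx$sequence,
       sequence_printed = if (!is.null(fx$sequence_printed)) fx$sequence_printed else fx$sequence,
       dotbracket = fx$dotbracket, native = native, pk_free = fx$pk_free,
       notes = fx$notes)
}

#' @rdname get_fixture
#' @export
fixture_ids <- function() names(FIXTURES)

#' Generate a synthetic hairpin
#'
#' A Watson-Crick stem of `stem_len` pairs around an all-A loop of
#' `loop_len` bases: each 5'-half stem base is mirrored by its complement in
#' the 3' half, so the native pairs are exactly the stem rungs and always
#' legal (the loop must hold at least 3 bases to satisfy the minimum
#' separation rule).
#'
#' @param stem_len Number of stem pairs (>= 1).
#' @param loop_len Loop length (>= 3).
#' @param bases 5'-half stem bases; default all-G (complement all-C). Pass
#'   `NULL` to draw them uniformly from A/U/C/G.
#' @return List with `seq` ([rna_sequence()]) and `native`
#'   ([secondary_structure()]): pairs `(k, 2*stem_len + loop_len + 1 - k)`.
#' @export
gen_hairpin <- function(stem_len, loop_len, bases = rep("G", stem_len)) {
  stopifnot(stem_len >= 1L)
  if (loop_len < 3L) stop("loop_len must be >= 3 to satisfy the minimum pair separation")
  if (is.null(bases)) bases <- sample(RNA_BASES, stem_len, replace = TRUE)
  stopifnot(length(bases) == stem_len)
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  seq <- rna_sequence(paste0(paste(bases, collapse = ""),
                             strrep("A", loop_len),
                             paste(rev(comp[bases]), collapse = "")))
  n <- 2L * stem_len + loop_len
  pairs <- cbind(seq_len(stem_len), n + 1L - seq_len(stem_len))
  list(seq = seq, native = secondary_structure(pairs))
}
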