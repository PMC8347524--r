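test_that("sequences normalize and validate", {
  s <- rna_sequence("gauc")
  expect_equal(as.character(s), "GAUC")
  expect_equal(seq_length(s), 4L)
  expect_equal(seq_codes(rna_sequence("AUCG")), 1:4)
  expect_equal(as.character(rna_sequence("GATTC")), "GAUUC")  # T -> U
  expect_error(rna_sequence("GANC"), "invalid RNA character 'N' at position 3")
  expect_error(rna_sequence(""), "empty")
})

test_that("dot-bracket parsing recovers printed pair lists", {
  s <- parse_dotbracket(".((.((.(((...)))(((....)))))))")
  expect_equal(s$pairs, as_pairs(rbind(
    c(2, 30), c(3, 29), c(5, 28), c(6, 27), c(8, 16), c(9, 15), c(10, 14),
    c(17, 26), c(18, 25), c(19, 24))))
  expect_true(all(s$layers == 0L))
  expect_equal(n_pairs(parse_dotbracket("...")), 0L)
})

test_that("pseudoknot layers parse with independent stacks", {
  s <- parse_dotbracket("((..[[..))..]]")
  expect_equal(s$pairs, as_pairs(rbind(c(1, 10), c(2, 9), c(5, 14), c(6, 13))))
  expect_equal(sum(s$layers == 1L), 2L)
  y26 <- get_fixture("1Y26")
  sq <- parse_dotbracket(y26$dotbracket)
  expect_equal(sum(sq$layers >= 1L), 3L)   # exactly three pseudoknot pairs
  expect_equal(n_pairs(sq), 25L)
})

test_that("unbalanced brackets fail with layer and position", {
  expect_error(parse_dotbracket("((..)"), "unmatched '\\(' \\(layer 0\\) at position 1")
  expect_error(parse_dotbracket("..)"), "unmatched '\\)' \\(layer 0\\) at position 3")
  expect_error(parse_dotbracket("[..(..)"), "layer 1")
  expect_error(parse_dotbracket("(x)"), "invalid dot-bracket character")
})

test_that("spaces inside dot-brackets are stripped before parsing", {
  a <- parse_dotbracket("(( ..\t))")
  b <- parse_dotbracket("((..))")
  expect_equal(structure_distance(a, b), 0L)
})

test_that("write_dotbracket inverts parse_dotbracket", {
  expect_equal(write_dotbracket(secondary_structure(), 4), "....")
  expect_equal(write_dotbracket(secondary_structure(rbind(c(1, 5))), 5), "(...)")
  db <- ".((.((.(((...)))(((....)))))))"
  expect_equal(write_dotbracket(parse_dotbracket(db), 30), db)
  expect_error(write_dotbracket(secondary_structure(rbind(c(1, 9))), 5), "exceeds")
})

test_that("parse/write round-trip holds on 1000 random nested structures", {
  set.seed(7)
  for (k in 1:1000) {
    L <- sample(5:40, 1)
    s <- random_nested_structure(L)
    rt <- parse_dotbracket(write_dotbracket(s, L))
    expect_identical(rt$pairs, s$pairs)
  }
})

test_that("secondary_structure enforces its invariants", {
  expect_error(secondary_structure(rbind(c(1, 5), c(5, 9))), "more than one pair")
  expect_error(secondary_structure(rbind(c(1, 6), c(3, 9))), "non-crossing")
  # crossing allowed across layers
  s <- secondary_structure(rbind(c(1, 6), c(3, 9)), layers = c(0, 1))
  expect_equal(n_pairs(s), 2L)
})

test_that("contact matrices are strictly upper-triangular with |pairs| ones", {
  expect_equal(sum(pairs_to_matrix(secondary_structure(), 6)), 0L)
  m <- pairs_to_matrix(secondary_structure(rbind(c(1, 5))), 5)
  expect_equal(which(m == 1L), 1L + 4L * 5L)  # row 1, col 5
  fx <- get_fixture("PDB_00972")
  mm <- pairs_to_matrix(fx$native, 30)
  expect_equal(sum(mm), 6L)
  expect_true(all(mm[lower.tri(mm, diag = TRUE)] == 0L))
  set.seed(11)
  for (k in 1:25) {
    s <- random_nested_structure(30)
    expect_equal(sum(pairs_to_matrix(s, 30)), n_pairs(s))
  }
})

test_that("structure_distance equals the pair-set symmetric difference and is a metric", {
  a <- parse_dotbracket("((...))")
  expect_equal(structure_distance(a, a), 0L)
  fx <- get_fixture("PDB_00972")
  expect_equal(structure_distance(fx$native, secondary_structure()), 6L)
  expect_equal(structure_distance(secondary_structure(rbind(c(1, 5))),
                                  secondary_structure(rbind(c(1, 6)))), 2L)
  set.seed(13)
  for (k in 1:50) {
    x <- random_nested_structure(25); y <- random_nested_structure(25)
    z <- random_nested_structure(25)
    expect_equal(structure_distance(x, y), structure_distance(y, x))
    expect_lte(structure_distance(x, z),
               structure_distance(x, y) + structure_distance(y, z))
  }
  pa <- parse_dotbracket("((...))")
  pb <- parse_dotbracket("(((...)))")
  expect_error(structure_distance(pa, pb), "different lengths")
})

test_that("dbn/bpseq/ct files round-trip", {
  fx <- get_fixture("hairpin30")
  rec <- list(name = "hairpin30", seq = rna_sequence(fx$sequence), struct = fx$native)
  for (fmt in c("dbn", "bpseq", "ct")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_structure_file(rec, path, fmt)
    back <- read_structure_file(path)
    expect_equal(as.character(back$seq), fx$sequence)
    expect_equal(structure_distance(back$struct, fx$native), 0L)
  }
})

test_that("all-zero partner columns give empty structures", {
  p1 <- tempfile(fileext = ".bpseq")
  writeLines(sprintf("%d A 0", 1:8), p1)
  expect_equal(n_pairs(read_structure_file(p1)$struct), 0L)
  p2 <- tempfile(fileext = ".ct")
  writeLines(c("5 empty", sprintf("%d A %d %d 0 %d", 1:5, 0:4, c(2:5, 0), 1:5)), p2)
  expect_equal(n_pairs(read_structure_file(p2)$struct), 0L)
})

test_that("FASTA reading normalizes sequences", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ggaUUcc", ">b", "ACGT"), fa)
  seqs <- read_fasta(fa)
  expect_equal(names(seqs), c("a", "b"))
  expect_equal(as.character(seqs$a), "GGAUUCC")
  expect_equal(as.character(seqs$b), "ACGU")   # T -> U
  ex <- system.file("extdata", "hairpin30.dbn", package = "rnafoldpath")
  rec <- read_structure_file(ex)
  expect_equal(n_pairs(rec$struct), 10L)
})

test_that("non-reciprocal pairing rows are rejected", {
  p <- tempfile(fileext = ".bpseq")
  writeLines(c("1 G 6", "2 A 0", "3 A 0", "4 A 0", "5 A 0", "6 C 0"), p)
  expect_error(read_structure_file(p), "not reciprocal")
})
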