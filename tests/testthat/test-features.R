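test_that("amino-acid composition matches the definition and the counting oracle", {
  expect_equal(unname(aac("AAAA")[1, ]), c(100, rep(0, 19)))
  expect_equal(unname(aac("ACDE")[1, c("A", "C", "D", "E")]), rep(25, 4))
  expect_equal(ncol(aac("ACDE")), 20L)
  expect_error(aac(""), "empty")
  seqs <- random_peptides(200, seed = 101)
  m <- aac(seqs)
  expect_equal(unname(rowSums(m)), rep(100, 200), tolerance = 1e-12)
  for (i in c(1, 50, 200)) {
    expect_identical(unname(m[i, ]), unname(oracle_aac(seqs[i])))
  }
  # composition is order-free: reversal leaves it unchanged
  rev_seqs <- vapply(strsplit(seqs, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, "")
  expect_equal(aac(rev_seqs), aac(seqs), ignore_attr = TRUE)
})

test_that("dipeptide composition uses N-1 overlapping windows and sums to 100", {
  expect_equal(unname(dpc("AAA")[1, "AA"]), 100)
  expect_equal(unname(dpc("ACAC")[1, c("AC", "CA")]),
               c(200 / 3, 100 / 3), tolerance = 1e-12)
  expect_equal(ncol(dpc("ACDE")), 400L)
  expect_equal(colnames(dpc("AC"))[1:3], c("AA", "AC", "AD"))
  expect_error(dpc("A"), "length")
  seqs <- random_peptides(200, seed = 102)
  m <- dpc(seqs)
  expect_equal(unname(rowSums(m)), rep(100, 200), tolerance = 1e-9)
  for (i in c(3, 77, 150)) {
    expect_equal(unname(m[i, ]), unname(oracle_dpc(seqs[i])),
                 tolerance = 1e-12)
  }
  # dipeptide composition is order-sensitive, unlike plain composition
  expect_false(isTRUE(all.equal(dpc("ACCC"), dpc("CCCA"),
                                check.attributes = FALSE)))
})

test_that("terminus subsequences slice as specified, with overlapping joins", {
  expect_equal(terminus_subsequence("ACDEFGHIKL", "N", 5), "ACDEF")
  expect_equal(terminus_subsequence("ACDEFGHIKL", "C", 5), "GHIKL")
  # k <= L < 2k: joined windows overlap in the middle
  expect_equal(terminus_subsequence("ACDEFGH", k = 5, join = TRUE),
               paste0(substr("ACDEFGH", 1, 5), substr("ACDEFGH", 3, 7)))
  expect_error(terminus_subsequence("ACD", "N", 5), "shorter")
  expect_error(terminus_subsequence("ACDEFGH", "N", 7), "k must be")
})

test_that("split composition encodes the terminus subsequence", {
  expect_equal(unname(split_composition("AAAAACCCCC", "N", 5)[1, "A"]), 100)
  m <- split_composition("AAAAACCCCC", k = 5, join = TRUE)
  expect_equal(unname(m[1, c("A", "C")]), c(50, 50))
  expect_equal(attr(m, "scheme"), "aac_N5C5")
  expect_equal(unname(split_composition("GGGGGAAAAA", "C", 5,
                                        order = "dpc")[1, "AA"]), 100)
})

test_that("binary profiles are one-hot per position in alphabetical order", {
  b <- binary_profile("ACDEF", "N5")
  expect_equal(unname(b[1, 1:20]), c(1, rep(0, 19)))  # A block
  expect_equal(unname(b[1, 21:40]), c(0, 1, rep(0, 18)))  # C block
  expect_equal(dim(b), c(1L, 100L))
  seqs <- random_peptides(50, min_len = 12, seed = 103)
  b10 <- binary_profile(seqs, "N10C10")
  expect_equal(ncol(b10), 400L)
  expect_true(all(b10 %in% c(0, 1)))
  # exactly one bit set per encoded position
  expect_equal(unname(rowSums(b10)), rep(20, 50))
  blocks <- matrix(seq_len(400), nrow = 20)
  for (j in seq_len(20)) {
    expect_equal(unname(rowSums(b10[, blocks[, j]])), rep(1, 50))
  }
  # substituting one encoded residue moves exactly two bits
  b1 <- binary_profile("ACDEFGHIKLMN", "N5")
  b2 <- binary_profile("AWDEFGHIKLMN", "N5")
  expect_equal(sum(b1 != b2), 2L)
  expect_error(binary_profile("ACD", "N5"), "shorter")
  expect_error(binary_profile("ACDEF", "Q5"), "unknown")
})

test_that("dataset encoding skips too-short peptides and reports them", {
  p <- peptide_set(c("long", "short"), c("ACDEFGHIKLMN", "ACD"))
  expect_warning(e <- encode_peptides(p, "binary_N5C5"), "skipped")
  expect_equal(rownames(e$features), "long")
  expect_equal(e$skipped$id, "short")
  expect_equal(e$peptides$id, "long")
  e2 <- encode_peptides(p, "aac")
  expect_equal(nrow(e2$features), 2L)
  expect_equal(nrow(e2$skipped), 0L)
  expect_error(encode_peptides(p, "tripeptide"), "unknown")
})

test_that("feature matrices export as headered delimited text", {
  p <- peptide_set(c("a", "b"), c("ACDE", "FGHI"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features(encode_peptides(p, "aac")$features, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(back$id, c("a", "b"))
  expect_equal(back$A, c(25, 0))
})
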