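test_that("random negatives match positive lengths, avoid positives, and reproduce", {
  pos <- peptide_set(paste0("p", 1:40),
                     random_peptides(40, min_len = 8, max_len = 30,
                                     seed = 201))
  bg <- generate_background_peptides(100, c(60L, 120L), seed = 202,
                                     prefix = "src")
  neg <- sample_random_negatives(bg, pos, 40, seed = 203)
  expect_equal(nrow(neg), 40L)
  expect_equal(anyDuplicated(neg$sequence), 0L)
  expect_length(intersect(neg$sequence, pos$sequence), 0)
  expect_true(all(nchar(neg$sequence) %in% nchar(pos$sequence)))
  neg2 <- sample_random_negatives(bg, pos, 40, seed = 203)
  expect_identical(neg, neg2)
  expect_equal(nrow(sample_random_negatives(bg, pos, 0)), 0L)
  short_bg <- peptide_set("one", "ACDEF")
  long_pos <- peptide_set("p", paste(rep("A", 30), collapse = ""))
  expect_error(sample_random_negatives(short_bg, long_pos, 3), "background")
})

test_that("capping fragments per protein yields non-overlapping negatives", {
  pos <- peptide_set(paste0("p", 1:30),
                     random_peptides(30, min_len = 10, max_len = 20,
                                     seed = 204))
  bg <- generate_background_peptides(40, c(50L, 80L), seed = 205,
                                     prefix = "src")
  neg <- sample_random_negatives(bg, pos, 30, seed = 206,
                                 max_per_protein = 1)
  hosts <- vapply(neg$sequence, function(f) {
    which(vapply(bg$sequence, function(p) grepl(f, p, fixed = TRUE),
                 logical(1)))[1]
  }, 0L)
  expect_equal(anyDuplicated(hosts), 0L)
})

test_that("similar-negative matching is greedy nearest-neighbour without replacement", {
  pos <- peptide_set("p1", "AACC")
  pool <- peptide_set(c("n1", "n2"), c("CACA", "GGGG"))
  sel <- build_similar_negatives(pos, pool)
  expect_equal(sel$sequence, "CACA")  # identical composition, distance 0
  expect_equal(attr(sel, "matched_distance"), 0)
  # hand-computed two-coordinate Euclidean distance
  d <- sqrt(sum((aac("AAAA") - aac("CCCC"))^2))
  expect_equal(d, sqrt(100^2 + 100^2), tolerance = 1e-12)
  # three positives, three candidates: perfect matching, each used once
  pos3 <- peptide_set(paste0("p", 1:3), c("AAAA", "CCCC", "GGGG"))
  pool3 <- peptide_set(paste0("n", 1:3), c("GGGC", "AAAC", "CCCA"))
  sel3 <- build_similar_negatives(pos3, pool3)
  expect_setequal(sel3$id, pool3$id)
  expect_equal(sel3$sequence, c("AAAC", "CCCA", "GGGC"))
  expect_error(build_similar_negatives(pool3, pos), "pool")
})

test_that("matched negatives are closer in composition than a random matching", {
  pos <- generate_signal_peptides(60, signal_spec(effect_size = 1),
                                  seed = 207)
  pool <- generate_background_peptides(600, seed = 208)
  hard <- build_similar_negatives(pos, pool)
  set.seed(209)
  rand <- pool[sample.int(nrow(pool), 60), ]
  dist_to <- function(neg) {
    mean(sqrt(rowSums((aac(pos) - aac(neg))^2)))
  }
  expect_lt(dist_to(hard), dist_to(rand))
})

test_that("the 80/20 split uses the floor convention, stratified by class", {
  pos <- peptide_set(paste0("p", 1:875), random_peptides(875, seed = 210))
  neg <- peptide_set(paste0("n", 1:875), random_peptides(875, seed = 211))
  neg <- neg[!(neg$sequence %in% pos$sequence), ]
  pos <- pos[seq_len(875 - (875 - nrow(neg))), ]  # keep classes equal
  ds <- split_train_validation(benchmark_dataset(pos, neg), 0.8, seed = 212)
  p <- ds$peptides
  for (cls in c("positive", "negative")) {
    expect_equal(sum(p$label == cls & p$split == "train"),
                 floor(0.8 * sum(p$label == cls)))
  }
  # 875 at 0.8 -> 700 train / 175 validation
  expect_equal(sum(p$label == "positive" & p$split == "train"), 700L)
  expect_equal(sum(p$label == "positive" & p$split == "validation"), 175L)
  # fraction 0.5 on 4 -> 2/2
  small <- split_train_validation(
    benchmark_dataset(peptide_set(paste0("a", 1:4),
                                  c("AAAA", "CCCC", "GGGG", "YYYY")),
                      peptide_set(paste0("b", 1:4),
                                  c("AAAC", "CCCG", "GGGY", "YYYA"))),
    0.5, seed = 213)
  expect_equal(sum(small$peptides$split == "train"), 4L)
  expect_error(split_train_validation(small, 1.2), "fraction")
})

test_that("five folds partition the training set into near-equal stratified blocks", {
  ds <- generate_benchmark(220, 220, signal_spec(effect_size = 1), seed = 214)
  p <- ds$peptides
  tr <- p[p$split == "train", ]
  expect_true(all(!is.na(tr$fold)))
  expect_true(all(is.na(p$fold[p$split == "validation"])))
  for (cls in c("positive", "negative")) {
    sizes <- table(tr$fold[tr$label == cls])
    expect_length(sizes, 5L)
    expect_lte(diff(range(sizes)), 1)
  }
  # same seed reproduces the whole dataset byte-identically
  ds2 <- generate_benchmark(220, 220, signal_spec(effect_size = 1),
                            seed = 214)
  expect_identical(ds$peptides, ds2$peptides)
})

test_that("benchmarks serialize to FASTA + fold table and load back losslessly", {
  ds <- generate_benchmark(60, 60, signal_spec(effect_size = 1), seed = 215)
  dir <- withr::local_tempdir()
  write_benchmark(ds, dir)
  back <- read_benchmark(dir)
  a <- ds$peptides[order(ds$peptides$id), c("id", "sequence", "label",
                                            "split", "fold")]
  b <- back$peptides[order(back$peptides$id), c("id", "sequence", "label",
                                                "split", "fold")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
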