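#' Assemble a labelled benchmark dataset
#'
#' Wraps positive and negative peptide sets into a single benchmark object.
#' Positives and negatives must be disjoint by sequence. The train/validation
#' split and fold assignment start empty; see [split_train_validation()] and
#' [assign_five_folds()].
#'
#' @param positives,negatives Peptide sets (see [peptide_set()]).
#' @return Object of class \code{"peptide_benchmark"}: list with
#'   \code{peptides} (a peptide set with \code{label}, \code{split} and
#'   \code{fold} columns) and \code{seed}.
#' @export
benchmark_dataset <- function(positives, negatives) {
  if (length(intersect(positives$sequence, negatives$sequence)) > 0) {
    stop("positive and negative sets share sequences")
  }
  pos <- positives; pos$label <- "positive"
  neg <- negatives; neg$label <- "negative"
  all <- rbind(pos, neg)
  if (anyDuplicated(all$id)) {
    all$id <- make.unique(all$id, sep = "_")
    warning("duplicate ids across classes; numeric suffixes appended")
  }
  all$split <- NA_character_
  all$fold <- NA_integer_
  structure(list(peptides = all, seed = NA_integer_),
            class = "peptide_benchmark")
}

#' @export
print.peptide_benchmark <- function(x, ...) {
  p <- x$peptides
  cat(sprintf("peptide benchmark: %d positives, %d negatives\n",
              sum(p$label == "positive"), sum(p$label == "negative")))
  if (!all(is.na(p$split))) {
    cat(sprintf("split: %d train / %d validation\n",
                sum(p$split == "train"), sum(p$split == "validation")))
  }
  if (!all(is.na(p$fold))) {
    cat("folds:", paste(table(p$fold), collapse = "/"), "\n")
  }
  invisible(x)
}

#' Sample random-background negatives
#'
#' Draws \code{n} negative peptides by repeatedly picking a background
#' protein uniformly at random and extracting a contiguous fragment whose
#' length is drawn uniformly from the multiset of positive lengths, so the
#' negative length distribution matches the positives and length cannot act
#' as a trivial discriminative leak. Fragments identical to any positive
#' sequence, or to an already-drawn negative, are rejected and resampled.
#'
#' @param background Peptide set of source proteins (each >= 5 residues).
#' @param positives Positive peptide set whose lengths are matched.
#' @param n Number of negatives to draw.
#' @param seed Integer seed.
#' @param max_tries Retry budget before giving up.
#' @param max_per_protein Cap on fragments extracted from any one protein;
#'   set to 1 to guarantee non-overlapping negatives (overlapping fragments
#'   of one protein are near-duplicates that leak across cross-validation
#'   folds).
#' @return Peptide set of \code{n} unique negatives (ids \code{neg_1..n}).
#' @export
sample_random_negatives <- function(background, positives, n, seed = 1,
                                    max_tries = 200 * max(n, 1),
                                    max_per_protein = Inf) {
  if (n == 0) return(peptide_set(character(), character()))
  if (nrow(background) == 0) stop("empty background")
  if (any(nchar(background$sequence) < 5)) {
    stop("background proteins must be at least 5 residues")
  }
  pos_lengths <- nchar(positives$sequence)
  if (max(nchar(background$sequence)) < min(pos_lengths)) {
    stop("background proteins shorter than the shortest positive")
  }
  forbidden <- unique(positives$sequence)
  bg_len <- nchar(background$sequence)
  uses <- integer(nrow(background))
  with_seed(seed, {
    out <- character(0)
    tries <- 0
    while (length(out) < n) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("background too small to yield ", n, " distinct fragments")
      }
      # draw the fragment length first so the negative length distribution
      # matches the positives exactly, then pick uniformly among proteins
      # long enough to host it
      len <- pos_lengths[sample.int(length(pos_lengths), 1)]
      eligible <- which(bg_len >= len & uses < max_per_protein)
      if (length(eligible) == 0) next
      pi <- eligible[sample.int(length(eligible), 1)]
      prot <- background$sequence[pi]
      L <- nchar(prot)
      start <- sample.int(L - len + 1, 1)
      frag <- substr(prot, start, start + len - 1)
      if (frag %in% forbidden || frag %in% out) next
      uses[pi] <- uses[pi] + 1
      out <- c(out, frag)
    }
    peptide_set(paste0("neg_", seq_len(n)), out, label = "negative")
  })
}

#' Build compositionally-similar hard negatives
#'
#' For each positive (in input order) selects the as-yet-unused candidate
#' whose amino-acid composition has the smallest Euclidean distance to the
#' positive's composition; greedy, without replacement, ties broken by the
#' lexicographically smallest candidate id. This yields negatives that are
#' deliberately hard to tell apart from positives by composition alone.
#'
#' @param positives Positive peptide set.
#' @param candidate_pool Peptide set of candidate negatives; must be at
#'   least as large as \code{positives}.
#' @return Peptide set of selected negatives, aligned with the positives'
#'   order, with a \code{matched_distance} attribute (per-pair AAC Euclidean
#'   distance).
#' @export
build_similar_negatives <- function(positives, candidate_pool) {
  if (nrow(candidate_pool) < nrow(positives)) {
    stop("candidate pool smaller than the positive set")
  }
  pa <- aac(positives)
  ca <- aac(candidate_pool)
  used <- rep(FALSE, nrow(ca))
  pick <- integer(nrow(pa))
  dist_picked <- numeric(nrow(pa))
  ids <- candidate_pool$id
  for (i in seq_len(nrow(pa))) {
    d <- sqrt(colSums((t(ca) - pa[i, ])^2))
    d[used] <- Inf
    cand <- which(d == min(d))
    if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
    pick[i] <- cand
    dist_picked[i] <- d[cand]
    used[cand] <- TRUE
  }
  out <- candidate_pool[pick, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "matched_distance") <- dist_picked
  out
}

#' Stratified train/validation split
#'
#' Randomly assigns, within each class, \code{floor(fraction * n)} peptides
#' to the training split and the remainder to validation (e.g. 875 positives
#' at the default 0.8 give 700 train / 175 validation).
#'
#' @param dataset A [benchmark_dataset()].
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return The benchmark with its \code{split} column filled in.
#' @export
split_train_validation <- function(dataset, fraction = 0.8, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  p <- dataset$peptides
  with_seed(seed, {
    for (cls in c("positive", "negative")) {
      idx <- which(p$label == cls)
      if (length(idx) < 2) stop("class ", cls, " has fewer than 2 peptides")
      n_train <- floor(fraction * length(idx))
      tr <- sample(idx, n_train)
      p$split[idx] <- "validation"
      p$split[tr] <- "train"
    }
  })
  dataset$peptides <- p
  dataset$seed <- seed
  dataset
}

#' Assign five stratified cross-validation folds
#'
#' Partitions the training split into 5 near-equal folds, stratified by
#' class (fold sizes within a class differ by at most 1), so that each fold
#' serves once as the held-out test set in the rotation.
#'
#' @param dataset A benchmark with a train/validation split.
#' @param seed Integer seed.
#' @param k Number of folds (default 5).
#' @return The benchmark with its \code{fold} column filled for training
#'   peptides.
#' @export
assign_five_folds <- function(dataset, seed = 1, k = 5) {
  p <- dataset$peptides
  if (all(is.na(p$split))) stop("split the dataset before assigning folds")
  with_seed(seed, {
    for (cls in c("positive", "negative")) {
      idx <- which(p$label == cls & p$split == "train")
      if (length(idx) < k) {
        stop("fewer than ", k, " training peptides in class ", cls)
      }
      shuffled <- sample(idx)
      p$fold[shuffled] <- rep_len(seq_len(k), length(idx))
    }
  })
  dataset$peptides <- p
  dataset
}

#' Extract an encoded design matrix from a benchmark
#'
#' Convenience accessor: encodes the requested split under a scheme and
#' returns the matrix, labels and (for training) fold assignment, rows
#' aligned.
#'
#' @param dataset A benchmark.
#' @param scheme Feature scheme name (see [encode_peptides()]).
#' @param split \code{"train"}, \code{"validation"} or \code{"all"}.
#' @return List with \code{features}, \code{labels}, \code{folds},
#'   \code{peptides}.
#' @export
benchmark_matrix <- function(dataset, scheme, split = c("train",
                                                        "validation",
                                                        "all")) {
  split <- match.arg(split)
  p <- dataset$peptides
  if (split != "all") p <- p[!is.na(p$split) & p$split == split, , drop = FALSE]
  enc <- encode_peptides(p, scheme)
  kept <- enc$peptides
  list(features = enc$features, labels = kept$label, folds = kept$fold,
       peptides = kept)
}

#' Serialize / load a benchmark as FASTA + fold table
#'
#' Writes four FASTA files (pos/neg x train/validation) plus a tab-separated
#' assignment table (\code{id}, \code{label}, \code{split}, \code{fold}) to
#' a directory, and reads them back losslessly.
#'
#' @param dataset A benchmark with split (and optionally folds) assigned.
#' @param dir Output directory (created if needed).
#' @param amidation_tag Optional tag for FASTA headers of amidated peptides.
#' @return \code{dir} invisibly; \code{read_benchmark} returns the
#'   benchmark.
#' @export
write_benchmark <- function(dataset, dir, amidation_tag = "amidated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- dataset$peptides
  for (cls in c("positive", "negative")) {
    for (sp in c("train", "validation")) {
      sub <- p[p$label == cls & !is.na(p$split) & p$split == sp, ,
               drop = FALSE]
      write_fasta(sub, file.path(dir, sprintf("%s_%s.fasta", cls, sp)),
                  amidation_tag = amidation_tag)
    }
  }
  utils::write.table(p[, c("id", "label", "split", "fold")],
                     file.path(dir, "assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(dir, amidation_tag = "amidated") {
  parts <- expand.grid(cls = c("positive", "negative"),
                       sp = c("train", "validation"),
                       stringsAsFactors = FALSE)
  peps <- do.call(rbind, lapply(seq_len(nrow(parts)), function(i) {
    f <- file.path(dir, sprintf("%s_%s.fasta", parts$cls[i], parts$sp[i]))
    q <- read_fasta(f, amidation_tag = amidation_tag)
    if (nrow(q) > 0) q$label <- parts$cls[i]
    q
  }))
  asg <- utils::read.table(file.path(dir, "assignments.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  m <- match(peps$id, asg$id)
  if (anyNA(m)) stop("assignment table does not cover all FASTA records")
  peps$split <- asg$split[m]
  peps$fold <- asg$fold[m]
  peps <- peps[order(match(peps$id, asg$id)), , drop = FALSE]
  rownames(peps) <- NULL
  structure(list(peptides = peps, seed = NA_integer_),
            class = "peptide_benchmark")
}
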