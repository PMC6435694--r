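#' All single-point mutants of a peptide
#'
#' Exhaustive in-silico saturation mutagenesis: every position substituted
#' by each of the 19 other residues, giving exactly \code{19 * L} mutants,
#' each differing from the original at exactly one position. Ids encode the
#' substitution as \code{<id>_<orig><pos><new>} (e.g. \code{p1_A3K}).
#'
#' @param peptide A single-row peptide set, or a single sequence string.
#' @return Peptide set of 19L mutants; the original peptide (flagged) is in
#'   the \code{"original"} attribute.
#' @export
single_mutants <- function(peptide) {
  pep <- as_single_peptide(peptide)
  s <- pep$sequence
  L <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ids <- character(0); seqs <- character(0)
  labels <- character(0)
  for (p in seq_len(L)) {
    for (r in setdiff(AA_ALPHA, ch[p])) {
      mut <- ch
      mut[p] <- r
      labels <- c(labels, sprintf("%s%d%s", ch[p], p, r))
      ids <- c(ids, sprintf("%s_%s%d%s", pep$id, ch[p], p, r))
      seqs <- c(seqs, paste(mut, collapse = ""))
    }
  }
  out <- peptide_set(ids, seqs, c_term_amidated = pep$c_term_amidated)
  attr(out, "original") <- pep
  attr(out, "mutation") <- labels
  out
}

#' Score and rank all single mutants of a peptide
#'
#' Scores the original peptide and all of its [single_mutants()] under a
#' trained model and returns them sorted by score (descending), supporting
#' iterative redesign: resubmit the top mutant to explore further.
#'
#' @param peptide A single-row peptide set or sequence string.
#' @param model An \code{npp_model} whose feature scheme is applicable to
#'   the peptide's length.
#' @param threshold Classification threshold.
#' @return data.frame with \code{id}, \code{sequence}, \code{mutation}
#'   (\code{"original"} for the input), \code{score}, \code{class};
#'   \code{19L + 1} rows.
#' @export
rank_mutants <- function(peptide, model, threshold = 0) {
  pep <- as_single_peptide(peptide)
  muts <- single_mutants(pep)
  all <- rbind(pep, muts)
  all$id[1] <- pep$id
  enc <- encode_peptides(all, model_scheme(model))
  if (nrow(enc$skipped) > 0) {
    stop("peptide too short for the model's feature scheme")
  }
  scores <- predict(model, enc$features)
  tab <- data.frame(id = all$id, sequence = all$sequence,
                    mutation = c("original", attr(muts, "mutation")),
                    score = scores,
                    class = ifelse(scores >= threshold, "positive",
                                   "negative"),
                    stringsAsFactors = FALSE)
  tab[order(-tab$score), , drop = FALSE]
}

#' Sliding-window scan of a protein
#'
#' Scores every overlapping window of the given length (stride 1) along a
#' protein, producing \code{L - w + 1} windows with 1-based inclusive
#' coordinates, to locate candidate neuropeptide-like regions.
#'
#' @param protein A single-row peptide set or sequence string.
#' @param window Window length (default 15); must not exceed the protein
#'   length.
#' @param model An \code{npp_model}.
#' @param threshold Classification threshold.
#' @return data.frame with \code{start}, \code{end}, \code{subsequence},
#'   \code{score}, \code{class}, sorted by position, plus a \code{"by_score"}
#'   attribute giving row indices in descending-score order.
#' @export
scan_protein <- function(protein, window = 15, model, threshold = 0) {
  pep <- as_single_peptide(protein)
  L <- nchar(pep$sequence)
  if (window > L) stop("window exceeds protein length")
  if (window < 1) stop("window must be >= 1")
  starts <- seq_len(L - window + 1L)
  subseq <- substring(pep$sequence, starts, starts + window - 1L)
  wins <- peptide_set(sprintf("%s_%d_%d", pep$id, starts,
                              starts + window - 1L), subseq)
  enc <- encode_peptides(wins, model_scheme(model))
  if (nrow(enc$skipped) > 0) {
    stop("window too short for the model's feature scheme")
  }
  scores <- predict(model, enc$features)
  tab <- data.frame(start = starts, end = starts + window - 1L,
                    subsequence = subseq, score = scores,
                    class = ifelse(scores >= threshold, "positive",
                                   "negative"),
                    stringsAsFactors = FALSE)
  attr(tab, "by_score") <- order(-tab$score)
  tab
}

model_scheme <- function(model) {
  if (is.null(model$feature_scheme)) {
    stop("model carries no feature scheme; train on encode_peptides() output")
  }
  model$feature_scheme
}

as_single_peptide <- function(x) {
  if (is.character(x) && length(x) == 1) {
    return(peptide_set("query", x))
  }
  if (is.data.frame(x) && nrow(x) == 1) return(x)
  stop("expected a single peptide (one-row peptide set or one sequence)")
}
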