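#' Mean residue composition of a peptide set
#'
#' Unweighted mean over peptides of the per-peptide amino-acid composition:
#' each peptide contributes equally regardless of its length.
#'
#' @param peptides Peptide set or character vector of sequences.
#' @return Named numeric vector of 20 percentages (sums to 100).
#' @export
mean_composition <- function(peptides) {
  colMeans(aac(peptides))
}

#' Per-residue composition difference between two sets
#'
#' \code{mean_composition(set_a) - mean_composition(set_b)}, used e.g. for
#' positive-vs-negative or insect-vs-human comparisons.
#'
#' @param set_a,set_b Peptide sets or sequence vectors.
#' @return Named numeric vector of 20 signed percentage differences
#'   (sums to 0).
#' @export
composition_difference <- function(set_a, set_b) {
  mean_composition(set_a) - mean_composition(set_b)
}

#' Positional residue composition at a terminus
#'
#' For the first five positions from the chosen terminus, the percentage of
#' peptides whose residue at that position is each amino acid. C-terminal
#' position 1 is the last residue. Peptides shorter than 5 residues are
#' skipped with a warning. Each row is a probability vector times 100.
#'
#' @param peptides Peptide set or sequence vector.
#' @param end \code{"N"} or \code{"C"}.
#' @param positions Positions from the terminus (default 1:5).
#' @return Matrix (positions x 20) of percentages.
#' @export
positional_composition <- function(peptides, end = c("N", "C"),
                                   positions = 1:5) {
  end <- match.arg(end)
  seqs <- as_sequences(peptides)
  need <- max(positions)
  short <- nchar(seqs) < need
  if (any(short)) {
    warning(sum(short), " peptide(s) shorter than ", need, " skipped")
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) stop("no peptides long enough")
  L <- nchar(seqs)
  m <- t(vapply(positions, function(p) {
    at <- if (end == "N") p else L - p + 1L
    ch <- substr(seqs, at, at)
    100 * tabulate(match(ch, AA_ALPHA), nbins = 20L) / length(seqs)
  }, numeric(20)))
  dimnames(m) <- list(paste0(end, positions), AA_ALPHA)
  m
}

#' Positional residue preference (positive minus negative)
#'
#' Difference of [positional_composition()] matrices between a positive and
#' a negative set; the row-wise argmax gives the residue most preferred at
#' each terminal position.
#'
#' @param pos_set,neg_set Peptide sets.
#' @param end \code{"N"} or \code{"C"}.
#' @param positions Positions from the terminus (default 1:5).
#' @return Matrix (positions x 20) of signed percentage differences, with a
#'   \code{"top_residue"} attribute giving the row-wise argmax.
#' @export
positional_preference <- function(pos_set, neg_set, end = c("N", "C"),
                                  positions = 1:5) {
  d <- positional_composition(pos_set, end, positions) -
    positional_composition(neg_set, end, positions)
  attr(d, "top_residue") <- colnames(d)[apply(d, 1, which.max)]
  d
}

#' Find motifs exclusive to the positive set
#'
#' Exact contiguous-substring miner: returns every substring of length
#' \code{min_len..max_len} present in at least \code{min_support} positive
#' peptides and in no negative peptide. Support counts peptides containing
#' at least one occurrence, not total occurrences. A motif wholly contained
#' in a returned longer motif with identical support is suppressed
#' (maximality filter). This is a transparent simplification of
#' discriminative-motif tools that use degenerate alphabets; only exact
#' residue patterns are mined.
#'
#' @param pos_set,neg_set Peptide sets or sequence vectors (non-empty).
#' @param min_len,max_len Motif length bounds (defaults 3 and 6).
#' @param min_support Minimum number of supporting positives.
#' @return data.frame with columns \code{pattern}, \code{positive_support},
#'   \code{negative_support} (always 0), sorted by support desc, length
#'   desc, then lexicographically.
#' @export
find_exclusive_motifs <- function(pos_set, neg_set, min_len = 3,
                                  max_len = 6, min_support = 2) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  pos <- as_sequences(pos_set)
  neg <- as_sequences(neg_set)
  if (length(pos) == 0 || length(neg) == 0) stop("both sets must be non-empty")
  sub_set <- function(s) {
    L <- nchar(s)
    out <- character(0)
    for (w in min_len:max_len) {
      if (L >= w) out <- c(out, substring(s, 1:(L - w + 1), w:L))
    }
    unique(out)
  }
  pos_subs <- lapply(pos, sub_set)
  support <- table(unlist(pos_subs))
  support <- support[support >= min_support]
  if (length(support) == 0) {
    return(data.frame(pattern = character(0), positive_support = integer(0),
                      negative_support = integer(0)))
  }
  neg_subs <- unique(unlist(lapply(neg, sub_set)))
  keep <- !(names(support) %in% neg_subs)
  support <- support[keep]
  pat <- names(support)
  sup <- as.integer(support)
  if (length(pat) > 0) {
    # maximality: drop motifs contained in a longer kept motif with the
    # same support
    ord <- order(nchar(pat), decreasing = TRUE)
    pat <- pat[ord]; sup <- sup[ord]
    drop <- rep(FALSE, length(pat))
    for (i in seq_along(pat)) {
      if (drop[i]) next
      longer <- which(nchar(pat) > nchar(pat[i]) & sup == sup[i] & !drop)
      if (any(vapply(pat[longer], function(m) grepl(pat[i], m, fixed = TRUE),
                     logical(1)))) {
        drop[i] <- TRUE
      }
    }
    pat <- pat[!drop]; sup <- sup[!drop]
  }
  ord <- order(-sup, -nchar(pat), pat)
  data.frame(pattern = pat[ord], positive_support = sup[ord],
             negative_support = rep(0L, length(pat)),
             stringsAsFactors = FALSE)
}
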