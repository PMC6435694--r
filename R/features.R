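#' Amino-acid composition (AAC)
#'
#' Percent composition of each of the 20 residues:
#' \code{Comp(i) = 100 * R_i / N}, where \code{R_i} is the count of residue
#' \code{i} and \code{N} the peptide length. Columns are in alphabetical
#' one-letter order and each row sums to 100.
#'
#' @param sequences Character vector of peptide sequences (or a peptide set,
#'   whose \code{sequence} column is used).
#' @return Numeric matrix, one row per peptide, 20 columns; attribute
#'   \code{scheme = "aac"}.
#' @examples
#' aac("ACDE")  # 25 each for A, C, D, E
#' @export
aac <- function(sequences) {
  sequences <- as_sequences(sequences)
  if (any(!nzchar(sequences))) stop("empty sequence has no composition")
  m <- t(vapply(strsplit(sequences, "", fixed = TRUE), function(ch) {
    100 * tabulate(match(ch, AA_ALPHA), nbins = 20L) / length(ch)
  }, numeric(20)))
  colnames(m) <- AA_ALPHA
  rownames(m) <- names(sequences)
  structure(m, scheme = "aac")
}

#' Dipeptide composition (DPC)
#'
#' Percent frequency of each of the 400 ordered residue pairs over the
#' peptide's \code{N - 1} overlapping length-2 windows:
#' \code{fraction(d) = 100 * count(d) / (N - 1)}. Columns are ordered
#' AA, AC, AD, ..., YW, YY and each row sums to 100.
#'
#' @inheritParams aac
#' @return Numeric matrix, one row per peptide, 400 columns; attribute
#'   \code{scheme = "dpc"}.
#' @examples
#' dpc("ACAC")  # AC: 66.67, CA: 33.33
#' @export
dpc <- function(sequences) {
  sequences <- as_sequences(sequences)
  n <- nchar(sequences)
  if (any(n < 2)) stop("dipeptide composition requires length >= 2")
  dips <- dipeptide_levels()
  m <- t(vapply(sequences, function(s) {
    L <- nchar(s)
    d <- paste0(substring(s, 1:(L - 1), 1:(L - 1)),
                substring(s, 2:L, 2:L))
    100 * tabulate(match(d, dips), nbins = 400L) / (L - 1)
  }, numeric(400), USE.NAMES = FALSE))
  colnames(m) <- dips
  rownames(m) <- names(sequences)
  structure(m, scheme = "dpc")
}

#' Extract a terminus subsequence
#'
#' Returns the first (\code{end = "N"}) or last (\code{end = "C"}) \code{k}
#' residues of each peptide, always in N-to-C order, or with
#' \code{join = TRUE} the concatenation first-k + last-k (the NkCk segment).
#' When \code{k <= L < 2k} the joined segment overlaps in the middle; a
#' peptide shorter than \code{k} is an error (dataset-level encoders skip
#' such peptides instead).
#'
#' @param sequences Character vector of sequences or a peptide set.
#' @param end \code{"N"} or \code{"C"}; ignored when \code{join = TRUE}.
#' @param k Window size, one of 5, 10, 15.
#' @param join Concatenate the N- and C-terminal windows.
#' @return Character vector of subsequences.
#' @export
terminus_subsequence <- function(sequences, end = c("N", "C"), k,
                                 join = FALSE) {
  sequences <- as_sequences(sequences)
  if (!k %in% c(5L, 10L, 15L)) stop("k must be one of 5, 10, 15")
  L <- nchar(sequences)
  if (any(L < k)) {
    stop(sprintf("peptide(s) shorter than k = %d: %s", k,
                 paste(utils::head(sequences[L < k], 5), collapse = ", ")))
  }
  if (join) {
    return(paste0(substr(sequences, 1L, k),
                  substr(sequences, L - k + 1L, L)))
  }
  end <- match.arg(end)
  if (end == "N") substr(sequences, 1L, k)
  else substr(sequences, L - k + 1L, L)
}

#' Terminus (split) composition
#'
#' AAC or DPC computed on a terminus subsequence: the first/last \code{k}
#' residues, or the joined NkCk segment. The joined composition is the
#' composition of the joined 2k-mer (a single 20- or 400-dim vector), not a
#' concatenation of two per-terminus vectors.
#'
#' @inheritParams terminus_subsequence
#' @param order \code{"aac"} (20-dim) or \code{"dpc"} (400-dim).
#' @return Feature matrix with a scheme attribute such as \code{"aac_N5"} or
#'   \code{"dpc_N10C10"}.
#' @export
split_composition <- function(sequences, end = c("N", "C"), k, join = FALSE,
                              order = c("aac", "dpc")) {
  order <- match.arg(order)
  sub <- terminus_subsequence(sequences, end, k, join)
  names(sub) <- names(as_sequences(sequences))
  m <- if (order == "aac") aac(sub) else dpc(sub)
  part <- if (join) sprintf("N%dC%d", k, k) else paste0(match.arg(end), k)
  structure(m, scheme = paste(order, part, sep = "_"))
}

#' Terminus binary profile
#'
#' One-hot encoding of a terminus window. Each position contributes a
#' 20-bit block (alphabetical order, so A is (1,0,...,0) and Y is
#' (0,...,0,1)); the blocks are concatenated N-to-C. \code{end_spec} is one
#' of N5/N10/N15, C5/C10/C15, or the joined N5C5/N10C10/N15C15 forms (e.g.
#' N10C10 gives 400 bits). Peptides shorter than the window are an error;
#' use [encode_peptides()] to skip them with a warning.
#'
#' @param sequences Character vector of sequences or a peptide set.
#' @param end_spec Window specifier string, e.g. \code{"N10C10"}.
#' @return Binary (0/1) matrix, one row per peptide; scheme attribute
#'   \code{paste0("binary_", end_spec)}.
#' @export
binary_profile <- function(sequences, end_spec) {
  sequences <- as_sequences(sequences)
  ps <- parse_end_spec(end_spec)
  win <- if (ps$join) {
    terminus_subsequence(sequences, k = ps$k, join = TRUE)
  } else {
    terminus_subsequence(sequences, end = ps$end, k = ps$k)
  }
  w <- ps$k * (if (ps$join) 2L else 1L)
  pos_labels <- if (ps$join) {
    c(paste0("N", seq_len(ps$k)), paste0("C", seq_len(ps$k)))
  } else {
    paste0(ps$end, seq_len(ps$k))
  }
  m <- t(vapply(strsplit(win, "", fixed = TRUE), function(ch) {
    b <- matrix(0, nrow = w, ncol = 20L)
    b[cbind(seq_len(w), match(ch, AA_ALPHA))] <- 1
    as.vector(t(b))
  }, numeric(20L * w), USE.NAMES = FALSE))
  colnames(m) <- paste(rep(pos_labels, each = 20L), AA_ALPHA, sep = "_")
  rownames(m) <- names(sequences)
  structure(m, scheme = paste0("binary_", end_spec))
}

parse_end_spec <- function(end_spec) {
  if (grepl("^N(5|10|15)C(5|10|15)$", end_spec)) {
    k1 <- as.integer(sub("^N(\\d+)C\\d+$", "\\1", end_spec))
    k2 <- as.integer(sub("^N\\d+C(\\d+)$", "\\1", end_spec))
    if (k1 != k2) stop("joined windows must use the same k on both ends")
    return(list(join = TRUE, end = NA_character_, k = k1))
  }
  if (grepl("^[NC](5|10|15)$", end_spec)) {
    return(list(join = FALSE, end = substr(end_spec, 1, 1),
                k = as.integer(substring(end_spec, 2))))
  }
  stop("unknown window specifier: ", end_spec)
}

# minimum peptide length required by a scheme
scheme_min_length <- function(scheme) {
  if (scheme == "aac") return(1L)
  if (scheme == "dpc") return(2L)
  part <- sub("^(aac|dpc|binary)_", "", scheme)
  ps <- parse_end_spec(part)
  base <- ps$k
  ord <- sub("_.*$", "", scheme)
  # a dpc on a k-mer needs k >= 2, already true for k in {5,10,15}
  base
}

#' Encode a peptide set under a named scheme
#'
#' Applies one encoder uniformly to a peptide set. Peptides too short for
#' the scheme are skipped with a warning and reported, so downstream rows
#' always align with the kept peptides.
#'
#' Recognised schemes: \code{"aac"}, \code{"dpc"},
#' \code{"aac_<win>"} / \code{"dpc_<win>"} / \code{"binary_<win>"} where
#' \code{<win>} is N5/N10/N15, C5/C10/C15 or N5C5/N10C10/N15C15.
#'
#' @param peptides A peptide set.
#' @param scheme Scheme name string.
#' @return A list with \code{features} (numeric matrix, rownames = ids),
#'   \code{peptides} (the kept rows) and \code{skipped} (data.frame of id and
#'   reason).
#' @examples
#' p <- peptide_set(c("a", "b"), c("ACDEFGHIKL", "ACD"))
#' encode_peptides(p, "aac")$features
#' @export
encode_peptides <- function(peptides, scheme) {
  if (!grepl("^(aac|dpc)$|^(aac|dpc|binary)_[NC]", scheme)) {
    stop("unknown feature scheme: ", scheme)
  }
  min_len <- scheme_min_length(scheme)
  too_short <- nchar(peptides$sequence) < min_len
  skipped <- data.frame(id = peptides$id[too_short],
                        reason = rep(sprintf("length < %d", min_len),
                                     sum(too_short)),
                        stringsAsFactors = FALSE)
  if (any(too_short)) {
    warning(sprintf("%d peptide(s) shorter than %d skipped for scheme %s",
                    sum(too_short), min_len, scheme))
  }
  kept <- peptides[!too_short, , drop = FALSE]
  seqs <- kept$sequence
  names(seqs) <- kept$id
  feats <- if (scheme == "aac") {
    aac(seqs)
  } else if (scheme == "dpc") {
    dpc(seqs)
  } else if (startsWith(scheme, "binary_")) {
    binary_profile(seqs, sub("^binary_", "", scheme))
  } else {
    ord <- sub("_.*$", "", scheme)
    part <- sub("^(aac|dpc)_", "", scheme)
    ps <- parse_end_spec(part)
    if (ps$join) split_composition(seqs, k = ps$k, join = TRUE, order = ord)
    else split_composition(seqs, end = ps$end, k = ps$k, order = ord)
  }
  list(features = structure(feats, scheme = scheme),
       peptides = kept, skipped = skipped)
}

#' Write a feature matrix as delimited text
#'
#' One row per peptide, id column first, tab-separated with a header.
#'
#' @param features Feature matrix with rownames (ids).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Accept either a peptide set data.frame or a character vector; names the
# result by id when available.
as_sequences <- function(x) {
  if (is.data.frame(x)) {
    s <- x$sequence
    names(s) <- x$id
    return(s)
  }
  stats::setNames(as.character(x), names(x))
}
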