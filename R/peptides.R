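#' Construct a validated peptide set
#'
#' A peptide set is a plain \code{data.frame} with columns \code{id},
#' \code{sequence}, \code{c_term_amidated} and \code{label}. Sequences are
#' uppercased and must use only the 20 natural amino acids; records carrying
#' non-natural residue codes (B, J, O, U, Z, X or anything else) are rejected.
#' Duplicate ids get a numeric suffix appended, with a warning.
#'
#' @param id Character vector of non-empty identifiers.
#' @param sequence Character vector of peptide sequences (case-insensitive).
#' @param c_term_amidated Logical, recycled; whether the C-terminus carries an
#'   amide modification.
#' @param label Optional class label per peptide: \code{"positive"},
#'   \code{"negative"} or \code{NA}.
#' @return A \code{data.frame} with one row per peptide.
#' @examples
#' peptide_set(c("p1", "p2"), c("acde", "FMRF"))
#' @export
peptide_set <- function(id, sequence, c_term_amidated = FALSE,
                        label = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("id and sequence must have the same length")
  }
  if (any(is.na(id)) || any(!nzchar(id))) stop("every id must be non-empty")
  bad <- validate_sequences(sequence)
  if (length(bad) > 0) {
    stop("invalid peptide sequence(s): ",
         paste(sprintf("%s [residues %s]", id[as.integer(names(bad))],
                       vapply(bad, paste, "", collapse = ",")),
               collapse = "; "))
  }
  if (anyDuplicated(id)) {
    id <- make.unique(id, sep = "_")
    warning("duplicate ids found; numeric suffixes appended")
  }
  label <- rep_len(as.character(label), length(id))
  ok <- is.na(label) | label %in% c("positive", "negative")
  if (!all(ok)) stop("label must be 'positive', 'negative' or NA")
  data.frame(id = id, sequence = sequence,
             c_term_amidated = rep_len(as.logical(c_term_amidated), length(id)),
             label = label, stringsAsFactors = FALSE)
}

# Returns a list keyed by offending index (as character) of the invalid
# residue letters in each bad sequence; empty list if all valid.
validate_sequences <- function(sequence) {
  ok <- nzchar(sequence) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
  bad <- which(!ok)
  out <- lapply(bad, function(i) {
    ch <- unique(strsplit(sequence[i], "", fixed = TRUE)[[1]])
    sort(setdiff(ch, AA_ALPHA))
  })
  names(out) <- as.character(bad)
  out
}

#' Read peptides from a FASTA file
#'
#' Reads a multi-record FASTA file into a peptide set. Sequences are
#' uppercased; records containing residues outside the 20-letter alphabet
#' (e.g. B, J, O, U, Z, X) are either skipped with a warning
#' (\code{strict = FALSE}, the default) or cause an error naming the record
#' and the offending residues (\code{strict = TRUE}). A malformed file whose
#' first record line is not a header raises a parse error naming the line.
#'
#' @param path Path to a FASTA file.
#' @param amidation_tag Optional token; if found in a record's description
#'   line (conventionally a \code{|}-delimited field, e.g.
#'   \code{>p1|amidated}), the peptide's \code{c_term_amidated} flag is set
#'   and the token is stripped from the id.
#' @param strict Fail on invalid records instead of skipping them.
#' @return A peptide set \code{data.frame} in file order.
#' @seealso [write_fasta()], [peptide_set()]
#' @export
read_fasta <- function(path, amidation_tag = NULL, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first)) {
    return(peptide_set(character(), character()))
  }
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: sequence before first header at line %d",
                 first))
  }
  recs <- Biostrings::readAAStringSet(path)
  headers <- names(recs)
  seqs <- toupper(as.character(recs))
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  amidated <- rep(FALSE, length(recs))
  if (!is.null(amidation_tag) && length(recs) > 0) {
    amidated <- grepl(amidation_tag, headers, fixed = TRUE)
    # strip the tag field from the id when present as a |-delimited token
    ids <- vapply(strsplit(ids, "|", fixed = TRUE), function(f) {
      paste(f[f != amidation_tag], collapse = "|")
    }, "")
  }
  bad <- validate_sequences(seqs)
  if (length(bad) > 0) {
    msg <- paste(sprintf("%s [residues %s]", ids[as.integer(names(bad))],
                         vapply(bad, paste, "", collapse = ",")),
                 collapse = "; ")
    if (strict) stop("invalid residues in FASTA record(s): ", msg)
    warning("skipping FASTA record(s) with invalid residues: ", msg)
    keep <- setdiff(seq_along(seqs), as.integer(names(bad)))
    ids <- ids[keep]; seqs <- seqs[keep]; amidated <- amidated[keep]
  }
  peptide_set(ids, seqs, c_term_amidated = amidated)
}

#' Write peptides to a FASTA file
#'
#' Inverse of [read_fasta()]: ids become headers, and amidated peptides get
#' the \code{amidation_tag} appended as a \code{|}-delimited field so the
#' flag round-trips.
#'
#' @param peptides A peptide set.
#' @param path Output file path.
#' @param amidation_tag Optional token appended to headers of amidated
#'   peptides.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(peptides, path, amidation_tag = NULL) {
  headers <- peptides$id
  if (!is.null(amidation_tag)) {
    headers <- ifelse(peptides$c_term_amidated,
                      paste(headers, amidation_tag, sep = "|"), headers)
  }
  x <- Biostrings::AAStringSet(peptides$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each exact sequence string, preserving
#' order. Sequences differing by even a single residue are both kept; no
#' similarity-threshold clustering is performed.
#'
#' @param peptides A peptide set.
#' @return The peptide set with exact duplicates removed.
#' @export
deduplicate <- function(peptides) {
  peptides[!duplicated(peptides$sequence), , drop = FALSE]
}
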