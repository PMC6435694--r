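#' The 20 natural amino acids
#'
#' One-letter codes of the 20 natural amino acids in alphabetical order.
#' This is the canonical feature order used by every encoder in the package,
#' so feature vectors are bit-comparable across runs.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# All 400 ordered dipeptides: AA, AC, AD, ..., YW, YY (first letter outermost).
dipeptide_levels <- function() {
  as.vector(t(outer(AA_ALPHA, AA_ALPHA, paste0)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomised operations in the package take explicit seeds through this,
# so no global random state leaks.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Sample n lengths uniformly from lo..hi (safe when lo == hi, where
# sample(lo:hi) would misbehave).
sample_lengths <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(lo:hi, n, replace = TRUE)
}

# Normalise labels to a logical is-positive vector. Accepts logicals,
# factors/characters with values "positive"/"negative", or 0/1.
is_positive_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative', logical, or 0/1")
  }
  labels == "positive"
}
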