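#' Signal specification for synthetic neuropeptide-like positives
#'
#' Describes the statistical structure planted into synthetic positives,
#' emulating what distinguishes insect neuropeptides from background
#' peptides: a global enrichment of a favored residue set (default C, D, E,
#' F, G, N, S, Y), per-position residue preferences at the first five
#' positions of each terminus (defaults N, F, D, S, I at the N-terminus and
#' L, F, N, G, L at the C-terminus, position 1 outermost), and optional
#' short motifs inserted with a given probability.
#'
#' All biases scale with \code{effect_size}: favored residues are weighted
#' \code{enrichment^effect_size} against 1 for the rest, and terminus/motif
#' probabilities are multiplied by \code{min(effect_size, 1)}. At
#' \code{effect_size = 0} positives are statistically exchangeable with the
#' uniform background.
#'
#' @param favored_residues Residues enriched in positives.
#' @param enrichment Base enrichment factor (>= 0) for favored residues.
#' @param n_term_pref,c_term_pref Preferred residues at terminal positions
#'   1..5 (position 1 outermost at each terminus).
#' @param terminus_pref_prob Per-position probability that the preferred
#'   residue is imposed (before effect-size scaling).
#' @param planted_motifs Named numeric vector: names are motif patterns,
#'   values insertion probabilities (before effect-size scaling).
#' @param length_range Integer length range, default 5..80.
#' @param effect_size Scalar (>= 0) scaling all biases; default 1.
#' @return Object of class \code{"signal_spec"}.
#' @export
signal_spec <- function(favored_residues = c("C", "D", "E", "F", "G", "N",
                                             "S", "Y"),
                        enrichment = 3,
                        n_term_pref = c("N", "F", "D", "S", "I"),
                        c_term_pref = c("L", "F", "N", "G", "L"),
                        terminus_pref_prob = 0.5,
                        planted_motifs = NULL,
                        length_range = c(5L, 80L),
                        effect_size = 1) {
  stopifnot(all(favored_residues %in% AA_ALPHA), enrichment >= 0,
            effect_size >= 0, terminus_pref_prob >= 0,
            terminus_pref_prob <= 1,
            length(length_range) == 2, length_range[1] >= 5,
            length_range[1] <= length_range[2])
  if (!is.null(planted_motifs)) {
    stopifnot(!is.null(names(planted_motifs)),
              all(planted_motifs >= 0 & planted_motifs <= 1),
              all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", names(planted_motifs))))
  }
  structure(list(favored_residues = favored_residues,
                 enrichment = enrichment,
                 n_term_pref = n_term_pref, c_term_pref = c_term_pref,
                 terminus_pref_prob = terminus_pref_prob,
                 planted_motifs = planted_motifs,
                 length_range = as.integer(length_range),
                 effect_size = effect_size),
            class = "signal_spec")
}

#' Signal specification for amidated neuropeptide-like positives
#'
#' Variant emulating C-terminally amidated neuropeptides: favored residues
#' D, E, F, G, M, N, P, R, S, Y; N-terminal preferences A, P, S, S, S and
#' C-terminal preferences L, R, P, F, F. Peptides generated under it carry
#' \code{c_term_amidated = TRUE}.
#'
#' @param ... Overrides passed to [signal_spec()].
#' @return A \code{signal_spec} with an \code{amidated} attribute.
#' @export
signal_spec_amidated <- function(...) {
  sp <- signal_spec(
    favored_residues = c("D", "E", "F", "G", "M", "N", "P", "R", "S", "Y"),
    n_term_pref = c("A", "P", "S", "S", "S"),
    c_term_pref = c("L", "R", "P", "F", "F"), ...)
  attr(sp, "amidated") <- TRUE
  sp
}

#' Generate uniform background peptides
#'
#' Residues are i.i.d. uniform over the 20 amino acids; lengths uniform over
#' the range. Stands in for random fragments of a generic proteome.
#'
#' @param n Number of peptides.
#' @param length_range Integer length range.
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return Peptide set of \code{n} peptides (ids \code{<prefix>_1..n}).
#' @export
generate_background_peptides <- function(n, length_range = c(5L, 80L),
                                         seed = 1, prefix = "bg") {
  if (n == 0) return(peptide_set(character(), character()))
  with_seed(seed, {
    lens <- sample_lengths(length_range[1], length_range[2], n)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHA, L, replace = TRUE), collapse = "")
    }, "")
    peptide_set(paste0(prefix, "_", seq_len(n)), seqs)
  })
}

#' Generate signal-bearing synthetic positives
#'
#' Draws residues from the enriched composition of a [signal_spec()], then
#' overrides the first five positions from each terminus with the spec's
#' per-position preferences (each applied independently with the scaled
#' preference probability; where the two termini overlap in short peptides,
#' the C-terminal preference wins), and finally inserts each planted motif
#' with its scaled probability at a uniform random position (in-place
#' substitution, preserving length).
#'
#' @param n Number of peptides.
#' @param spec A [signal_spec()].
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return Peptide set of \code{n} positives (labelled \code{"positive"};
#'   amidated when the spec carries the amidated attribute).
#' @export
generate_signal_peptides <- function(n, spec = signal_spec(), seed = 1,
                                     prefix = "pos") {
  if (n == 0) return(peptide_set(character(), character()))
  w <- rep(1, 20)
  names(w) <- AA_ALPHA
  w[spec$favored_residues] <- spec$enrichment^spec$effect_size
  prob <- w / sum(w)
  p_pref <- min(1, spec$terminus_pref_prob * min(spec$effect_size, 1))
  p_scale <- min(spec$effect_size, 1)
  with_seed(seed, {
    lens <- sample_lengths(spec$length_range[1], spec$length_range[2], n)
    seqs <- vapply(lens, function(L) {
      ch <- sample(AA_ALPHA, L, replace = TRUE, prob = prob)
      if (p_pref > 0) {
        for (p in seq_len(min(5L, L))) {
          if (stats::runif(1) < p_pref) ch[p] <- spec$n_term_pref[p]
        }
        for (p in seq_len(min(5L, L))) {
          if (stats::runif(1) < p_pref) ch[L - p + 1L] <- spec$c_term_pref[p]
        }
      }
      s <- paste(ch, collapse = "")
      for (m in names(spec$planted_motifs)) {
        q <- spec$planted_motifs[[m]] * p_scale
        wm <- nchar(m)
        if (wm <= L && stats::runif(1) < q) {
          at <- sample.int(L - wm + 1L, 1)
          substr(s, at, at + wm - 1L) <- m
        }
      }
      s
    }, "")
    peptide_set(paste0(prefix, "_", seq_len(n)), seqs,
                c_term_amidated = isTRUE(attr(spec, "amidated")),
                label = "positive")
  })
}

#' Generate a complete synthetic benchmark
#'
#' Positives come from [generate_signal_peptides()]; negatives either from
#' the uniform background with lengths drawn from the positive length
#' distribution (the default), or — with \code{hard_negatives = TRUE} — by
#' compositional matching ([build_similar_negatives()]) against an
#' oversampled background pool. Both classes are deduplicated and made
#' disjoint, then split 80/20 (stratified) and given five stratified folds.
#'
#' @param n_pos,n_neg Class sizes before deduplication.
#' @param spec A [signal_spec()].
#' @param hard_negatives Use compositionally-matched negatives.
#' @param seed Integer seed.
#' @param pool_factor Oversampling factor for the hard-negative candidate
#'   pool.
#' @return A [benchmark_dataset()] with split and folds assigned.
#' @export
generate_benchmark <- function(n_pos = 500, n_neg = n_pos,
                               spec = signal_spec(), hard_negatives = FALSE,
                               seed = 1, pool_factor = 5) {
  pos <- deduplicate(generate_signal_peptides(n_pos, spec, seed = seed))
  if (hard_negatives) {
    pool <- generate_background_peptides(pool_factor * n_neg,
                                         spec$length_range, seed = seed + 1)
    pool <- pool[!(pool$sequence %in% pos$sequence), , drop = FALSE]
    pool <- deduplicate(pool)
    neg <- build_similar_negatives(pos[seq_len(min(nrow(pos), n_neg)), ],
                                   pool)
    neg$id <- paste0("neg_", seq_len(nrow(neg)))
  } else {
    # background negatives, length-matched to the positives; long source
    # proteins and one fragment per protein keep negatives non-overlapping,
    # so at effect_size = 0 the two classes are exactly exchangeable
    src_len <- c(3L, 5L) * spec$length_range[2]
    bg <- generate_background_peptides(2 * n_neg, src_len, seed = seed + 1,
                                       prefix = "src")
    neg <- sample_random_negatives(bg, pos, n_neg, seed = seed + 2,
                                   max_per_protein = 1)
  }
  neg <- deduplicate(neg)
  neg <- neg[!(neg$sequence %in% pos$sequence), , drop = FALSE]
  ds <- benchmark_dataset(pos, neg)
  ds <- split_train_validation(ds, 0.8, seed = seed + 3)
  assign_five_folds(ds, seed = seed + 4)
}
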