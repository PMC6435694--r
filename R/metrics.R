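#' Confusion counts at a score threshold
#'
#' A score greater than or equal to the threshold predicts the positive
#' class.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels True labels (\code{"positive"}/\code{"negative"}, logical,
#'   or 0/1).
#' @param threshold Decision threshold.
#' @return Named list with integer \code{TP}, \code{TN}, \code{FP},
#'   \code{FN}.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  pos <- is_positive_label(labels)
  pred <- scores >= threshold
  confusion_counts(TP = sum(pred & pos), TN = sum(!pred & !pos),
                   FP = sum(pred & !pos), FN = sum(!pred & pos))
}

#' @rdname confusion_at_threshold
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- list(TP = as.numeric(TP), TN = as.numeric(TN),
                 FP = as.numeric(FP), FN = as.numeric(FN))
  if (any(unlist(counts) < 0)) stop("confusion counts must be non-negative")
  counts
}

#' Threshold-dependent performance measures
#'
#' Standard binary-classification measures computed from confusion counts:
#' \describe{
#'   \item{sensitivity}{\code{100 * TP / (TP + FN)}}
#'   \item{specificity}{\code{100 * TN / (TN + FP)}}
#'   \item{accuracy}{\code{100 * (TP + TN) / (TP + FP + TN + FN)}}
#'   \item{mcc}{Matthews correlation coefficient,
#'     \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}; returns 0
#'     when any factor of the denominator is 0 (standard convention).}
#' }
#' Sensitivity, specificity and accuracy are percentages; an empty class
#' yields \code{NaN} for the measures it makes undefined.
#'
#' @param counts Confusion counts from [confusion_counts()] or
#'   [confusion_at_threshold()].
#' @return Numeric scalar.
#' @examples
#' cc <- confusion_counts(TP = 144, TN = 149, FP = 26, FN = 31)
#' sensitivity(cc)  # 82.29
#' mcc(cc)          # 0.67
#' @export
sensitivity <- function(counts) {
  with(counts, 100 * TP / (TP + FN))
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  with(counts, 100 * TN / (TN + FP))
}

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  with(counts, 100 * (TP + TN) / (TP + FP + TN + FN))
}

#' @rdname sensitivity
#' @export
mcc <- function(counts) {
  with(counts, {
    den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (den == 0) return(0)
    ((TP * TN) - (FP * FN)) / sqrt(den)
  })
}

#' Area under the ROC curve
#'
#' Computed as the rank statistic: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted half.
#' This equals the trapezoidal area under the TPR-vs-FPR curve.
#'
#' @inheritParams confusion_at_threshold
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  if (anyNA(scores)) stop("scores contain missing values")
  pos <- is_positive_label(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties as half-wins
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate scores against labels at a threshold
#'
#' Bundles confusion counts, sensitivity, specificity, accuracy, MCC and
#' AUROC into one report.
#'
#' @inheritParams confusion_at_threshold
#' @return An object of class \code{"npp_eval"}: list with \code{threshold},
#'   \code{counts}, \code{sen}, \code{spc}, \code{acc}, \code{mcc},
#'   \code{auroc}.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0) {
  counts <- confusion_at_threshold(scores, labels, threshold)
  structure(list(threshold = threshold, counts = counts,
                 sen = sensitivity(counts), spc = specificity(counts),
                 acc = accuracy(counts), mcc = mcc(counts),
                 auroc = auroc(scores, labels)),
            class = "npp_eval")
}

#' @export
print.npp_eval <- function(x, ...) {
  cat(sprintf("threshold %.4g  TP %.0f TN %.0f FP %.0f FN %.0f\n", x$threshold,
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  cat(sprintf("Sen %.2f  Spc %.2f  Acc %.2f  MCC %.2f  AUROC %.2f\n",
              x$sen, x$spc, x$acc, x$mcc, x$auroc))
  invisible(x)
}

#' @export
as.data.frame.npp_eval <- function(x, ...) {
  data.frame(threshold = x$threshold, TP = x$counts$TP, TN = x$counts$TN,
             FP = x$counts$FP, FN = x$counts$FN, sen = x$sen, spc = x$spc,
             acc = x$acc, mcc = x$mcc, auroc = x$auroc)
}

#' Performance at every distinct-score threshold
#'
#' Evaluates the full set of distinct scores as candidate thresholds. The
#' threshold maximising accuracy (ties broken by the smallest
#' \code{|sen - spc|}, then the larger threshold) is recorded as the default
#' threshold in the \code{"default_threshold"} attribute; it is the
#' threshold exported with trained models.
#'
#' @inheritParams confusion_at_threshold
#' @return data.frame with one row per threshold and columns threshold, TP,
#'   TN, FP, FN, sen, spc, acc, mcc.
#' @export
threshold_sweep <- function(scores, labels) {
  ths <- sort(unique(scores))
  rows <- lapply(ths, function(t) {
    cc <- confusion_at_threshold(scores, labels, t)
    data.frame(threshold = t, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               sen = sensitivity(cc), spc = specificity(cc),
               acc = accuracy(cc), mcc = mcc(cc))
  })
  tab <- do.call(rbind, rows)
  best <- which(tab$acc == max(tab$acc))
  if (length(best) > 1) {
    bal <- abs(tab$sen[best] - tab$spc[best])
    best <- best[bal == min(bal)]
    # still tied (e.g. a fully separating gap): take the median candidate
    best <- best[ceiling(length(best) / 2)]
  }
  # cut midway between the winning score and the next-lower distinct score:
  # a threshold sitting exactly on an observed score generalises poorly
  attr(tab, "default_threshold") <-
    if (best == 1) ths[1] else (ths[best] + ths[best - 1]) / 2
  tab
}

#' Five-fold cross-validation of a model specification
#'
#' For each fold, trains on the other folds, picks the fold's default
#' threshold by [threshold_sweep()] on the training scores, and evaluates
#' the held-out fold at that threshold. Headline numbers are the unweighted
#' mean over folds; a pooled-score report is also computed for diagnostics.
#'
#' @param x Feature matrix.
#' @param labels Labels aligned with rows of \code{x}.
#' @param folds Integer fold assignment (1..k) aligned with rows, e.g. from
#'   [assign_five_folds()].
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling any stochastic learner.
#' @return Object of class \code{"npp_cv"}: list with \code{mean} (named
#'   vector sen/spc/acc/mcc/auroc), \code{per_fold} (list of
#'   \code{npp_eval}), \code{pooled} (\code{npp_eval}).
#' @export
cross_validate <- function(x, labels, folds, spec, seed = 1) {
  ks <- sort(unique(folds))
  pos <- is_positive_label(labels)
  per_fold <- vector("list", length(ks))
  pooled_scores <- numeric(length(labels))
  for (i in seq_along(ks)) {
    k <- ks[i]
    tr <- folds != k
    model <- npp_train(x[tr, , drop = FALSE], pos[tr], spec,
                       seed = seed + i)
    tr_scores <- predict(model, x[tr, , drop = FALSE])
    thr <- attr(threshold_sweep(tr_scores, pos[tr]), "default_threshold")
    te_scores <- predict(model, x[!tr, , drop = FALSE])
    pooled_scores[!tr] <- te_scores
    per_fold[[i]] <- evaluate_scores(te_scores, pos[!tr], thr)
  }
  mets <- sapply(per_fold, function(e) c(sen = e$sen, spc = e$spc,
                                         acc = e$acc, mcc = e$mcc,
                                         auroc = e$auroc))
  structure(list(mean = rowMeans(mets), per_fold = per_fold,
                 pooled = evaluate_scores(pooled_scores, pos, 0),
                 spec = spec),
            class = "npp_cv")
}

#' @export
print.npp_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", length(x$per_fold),
              x$spec$algorithm))
  cat(sprintf("mean: Sen %.2f  Spc %.2f  Acc %.2f  MCC %.2f  AUROC %.2f\n",
              x$mean["sen"], x$mean["spc"], x$mean["acc"], x$mean["mcc"],
              x$mean["auroc"]))
  invisible(x)
}
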