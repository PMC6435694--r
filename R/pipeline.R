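#' End-to-end training pipeline
#'
#' Reproduces the full training protocol on a pair of labelled peptide sets:
#' deduplicate each class, make them disjoint, stratified 80/20
#' train/validation split, five stratified folds, grid search by five-fold
#' cross-validation, final fit on the full training split, default threshold
#' from a threshold sweep of the training scores, and external evaluation on
#' the held-out validation split.
#'
#' @param positives,negatives Peptide sets.
#' @param scheme Feature scheme (see [encode_peptides()]).
#' @param algorithm Learner name (see [model_spec()]).
#' @param grid Hyperparameter grid; defaults to [default_grid()].
#' @param seed Integer seed controlling split, folds and learners.
#' @param fraction Training fraction (default 0.8).
#' @return Object of class \code{"npp_fit"}: list with \code{model} (the
#'   final \code{npp_model}), \code{threshold}, \code{cv} (winning
#'   \code{npp_cv}), \code{validation} (\code{npp_eval}), \code{grid}
#'   (\code{npp_grid}), \code{dataset} (the split benchmark) and
#'   \code{scheme}.
#' @export
train_pipeline <- function(positives, negatives, scheme = "dpc",
                           algorithm = "svm_rbf",
                           grid = default_grid(algorithm), seed = 1,
                           fraction = 0.8) {
  positives <- deduplicate(positives)
  negatives <- deduplicate(negatives)
  negatives <- negatives[!(negatives$sequence %in% positives$sequence), ,
                         drop = FALSE]
  ds <- benchmark_dataset(positives, negatives)
  ds <- split_train_validation(ds, fraction, seed = seed)
  ds <- assign_five_folds(ds, seed = seed + 1)
  tr <- benchmark_matrix(ds, scheme, "train")
  gs <- grid_search(tr$features, tr$labels, algorithm, grid, tr$folds,
                    seed = seed + 2)
  model <- npp_train(tr$features, tr$labels, gs$best_spec, seed = seed + 3)
  tr_scores <- predict(model, tr$features)
  threshold <- attr(threshold_sweep(tr_scores, tr$labels),
                    "default_threshold")
  va <- benchmark_matrix(ds, scheme, "validation")
  va_scores <- predict(model, va$features)
  structure(list(model = model, threshold = threshold, cv = gs$best_cv,
                 validation = evaluate_scores(va_scores, va$labels,
                                              threshold),
                 grid = gs, dataset = ds, scheme = scheme, seed = seed),
            class = "npp_fit")
}

#' @export
print.npp_fit <- function(x, ...) {
  cat("peptide activity model\n")
  print(x$model$spec)
  cat(sprintf("scheme %s, default threshold %.4g\n", x$scheme, x$threshold))
  cat("internal (five-fold CV, mean): ")
  cat(sprintf("Sen %.2f Spc %.2f Acc %.2f MCC %.2f AUROC %.2f\n",
              x$cv$mean["sen"], x$cv$mean["spc"], x$cv$mean["acc"],
              x$cv$mean["mcc"], x$cv$mean["auroc"]))
  cat("external (validation):        ")
  cat(sprintf("Sen %.2f Spc %.2f Acc %.2f MCC %.2f AUROC %.2f\n",
              x$validation$sen, x$validation$spc, x$validation$acc,
              x$validation$mcc, x$validation$auroc))
  invisible(x)
}

#' @export
summary.npp_fit <- function(object, ...) {
  rbind(cv_mean = object$cv$mean,
        validation = c(sen = object$validation$sen,
                       spc = object$validation$spc,
                       acc = object$validation$acc,
                       mcc = object$validation$mcc,
                       auroc = object$validation$auroc))
}

#' Train a bundled preset model on synthetic data
#'
#' Two presets mirror the two kinds of model the toolkit targets:
#' \code{"natural"} (DPC SVM on a synthetic benchmark of natural,
#' unmodified neuropeptide-like positives) and \code{"modified"} (DPC SVM
#' on a C-terminally amidated benchmark). Both are trained at call time on the
#' synthetic generator — they demonstrate the pipeline and serve as defaults
#' for the design/scan tools; retrain on real curated datasets for
#' production use.
#'
#' @param name \code{"natural"} or \code{"modified"}.
#' @param n Peptides per class in the synthetic benchmark.
#' @param seed Integer seed.
#' @return An \code{npp_fit}.
#' @export
preset_model <- function(name = c("natural", "modified"), n = 300,
                         seed = 42) {
  name <- match.arg(name)
  spec <- if (name == "natural") signal_spec(effect_size = 1.5)
          else signal_spec_amidated(effect_size = 1.5)
  pos <- generate_signal_peptides(n, spec, seed = seed)
  bg <- generate_background_peptides(4 * n, spec$length_range,
                                     seed = seed + 1, prefix = "src")
  neg <- sample_random_negatives(bg, pos, n, seed = seed + 2)
  small_grid <- expand.grid(g = c(5e-4, 1e-3, 5e-3), c = c(1, 5), j = 1)
  train_pipeline(pos, neg, scheme = "dpc", algorithm = "svm_rbf",
                 grid = small_grid, seed = seed + 3)
}
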