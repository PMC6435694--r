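#' Model specification
#'
#' Describes a learner and its hyperparameters.
#'
#' \describe{
#'   \item{svm_rbf}{RBF-kernel support vector machine with kernel width
#'     \code{g} (> 0), regularisation \code{c} (> 0) and positive-class cost
#'     factor \code{j} (>= 1): the misclassification cost of positives is
#'     \code{j} times that of negatives.}
#'   \item{linear_margin}{Linear-kernel margin classifier with the same
#'     \code{c}/\code{j} contract.}
#'   \item{random_forest}{Random forest with \code{ntree} trees.}
#'   \item{decision_tree}{Pruned classification tree; \code{c} is the
#'     complexity (pruning) parameter, \code{m} the minimum leaf size.}
#'   \item{naive_bayes}{Gaussian naive Bayes; no hyperparameters.}
#' }
#'
#' @param algorithm One of \code{"svm_rbf"}, \code{"linear_margin"},
#'   \code{"random_forest"}, \code{"decision_tree"}, \code{"naive_bayes"}.
#' @param ... Hyperparameters overriding the defaults above.
#' @return Object of class \code{"model_spec"}.
#' @examples
#' model_spec("svm_rbf", g = 0.001, c = 1, j = 4)
#' @export
model_spec <- function(algorithm = c("svm_rbf", "linear_margin",
                                     "random_forest", "decision_tree",
                                     "naive_bayes"), ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm_rbf = list(g = 0.01, c = 1, j = 1),
    linear_margin = list(c = 1, j = 1),
    random_forest = list(ntree = 70),
    decision_tree = list(c = 0.01, m = 7),
    naive_bayes = list())
  hp <- utils::modifyList(defaults, list(...))
  extra <- setdiff(names(hp), names(defaults))
  if (length(extra) > 0) {
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(extra, collapse = ", "))
  }
  if (!is.null(hp$g) && hp$g <= 0) stop("g must be > 0")
  if (!is.null(hp$c) && hp$c <= 0) stop("c must be > 0")
  if (!is.null(hp$j) && hp$j < 1) stop("j must be >= 1")
  if (!is.null(hp$ntree) && hp$ntree < 1) stop("ntree must be >= 1")
  structure(list(algorithm = algorithm, hyperparameters = hp),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("model_spec: %s (%s)\n", x$algorithm,
              if (nzchar(hp)) hp else "default"))
  invisible(x)
}

#' Train a binary peptide classifier
#'
#' Fits the learner described by a [model_spec()] on a feature matrix and
#' returns a scorer. Scores are signed margins for the SVM learners and
#' class-probability-of-positive minus 0.5 for the probabilistic learners,
#' so threshold 0 is a sensible default throughout. For \code{svm_rbf} and
#' \code{linear_margin} the \code{j} hyperparameter scales the
#' misclassification cost of the positive class.
#'
#' @param x Numeric feature matrix (rows = peptides), typically from
#'   [encode_peptides()]; its scheme attribute, when present, is recorded and
#'   enforced at predict time.
#' @param labels Labels aligned with rows; both classes must be present.
#' @param spec A [model_spec()].
#' @param seed Integer seed fixing any stochastic learner.
#' @return Object of class \code{"npp_model"} with a [predict.npp_model()]
#'   method.
#' @export
npp_train <- function(x, labels, spec = model_spec("svm_rbf"), seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix contains missing values")
  pos <- is_positive_label(labels)
  if (length(pos) != nrow(x)) stop("labels must align with feature rows")
  if (all(pos) || all(!pos)) stop("both classes must be present in training")
  y <- factor(ifelse(pos, "positive", "negative"),
              levels = c("positive", "negative"))
  hp <- spec$hyperparameters
  fit <- with_seed(seed, switch(spec$algorithm,
    svm_rbf = e1071::svm(
      x, y, kernel = "radial", gamma = hp$g, cost = hp$c, scale = FALSE,
      class.weights = c(positive = hp$j, negative = 1)),
    linear_margin = e1071::svm(
      x, y, kernel = "linear", cost = hp$c, scale = FALSE,
      class.weights = c(positive = hp$j, negative = 1)),
    random_forest = randomForest::randomForest(x, y, ntree = hp$ntree),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = y, x, check.names = TRUE),
      method = "class",
      control = rpart::rpart.control(cp = hp$c, minbucket = hp$m,
                                     minsplit = 2L * hp$m)),
    naive_bayes = fit_naive_bayes(x, y)))
  model <- structure(list(spec = spec, fit = fit, seed = seed,
                          feature_scheme = attr(x, "scheme"),
                          feature_names = colnames(x),
                          training_fingerprint = fingerprint_matrix(x, pos)),
                     class = "npp_model")
  model
}

fit_naive_bayes <- function(x, y) {
  # Gaussian NB degenerates on features that are constant within a class
  # (zero variance), common for sparse dipeptide columns; drop them.
  sds <- vapply(levels(y), function(l) {
    apply(x[y == l, , drop = FALSE], 2, stats::sd)
  }, numeric(ncol(x)))
  keep <- apply(sds, 1, function(s) all(s > 1e-9))
  if (!any(keep)) stop("no informative features for naive Bayes")
  fit <- e1071::naiveBayes(x[, keep, drop = FALSE], y)
  attr(fit, "kept_features") <- colnames(x)[keep]
  fit
}

fingerprint_matrix <- function(x, pos) {
  # cheap content hash: no digest dependency needed for a mismatch guard
  v <- c(dim(x), sum(x), sum(x * seq_along(x) %% 97), sum(pos))
  paste(format(v, digits = 15), collapse = "/")
}

#' Score peptides with a trained model
#'
#' Returns one finite real score per row (higher = more neuropeptide-like),
#' or the hard classification at a threshold. The feature scheme of
#' \code{newdata} must match the scheme the model was trained on.
#'
#' @param object An \code{npp_model} from [npp_train()].
#' @param newdata Feature matrix under the model's scheme.
#' @param type \code{"score"} (default) or \code{"class"}.
#' @param threshold Threshold for \code{type = "class"}.
#' @param ... Unused.
#' @return Numeric scores, or a character vector of
#'   \code{"positive"}/\code{"negative"}.
#' @export
predict.npp_model <- function(object, newdata, type = c("score", "class"),
                              threshold = 0, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  scheme <- attr(newdata, "scheme")
  if (!is.null(scheme) && !is.null(object$feature_scheme) &&
      !identical(scheme, object$feature_scheme)) {
    stop(sprintf("feature scheme mismatch: model trained on '%s', data is '%s'",
                 object$feature_scheme, scheme))
  }
  if (ncol(newdata) > 0 && !is.null(object$feature_names) &&
      ncol(newdata) != length(object$feature_names)) {
    stop("feature dimension mismatch")
  }
  if (nrow(newdata) == 0) return(numeric(0))
  if (anyNA(newdata)) stop("feature matrix contains missing values")
  scores <- score_matrix(object, newdata)
  if (type == "score") scores
  else ifelse(scores >= threshold, "positive", "negative")
}

score_matrix <- function(object, newdata) {
  alg <- object$spec$algorithm
  if (alg %in% c("svm_rbf", "linear_margin")) {
    p <- stats::predict(object$fit, newdata, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    s <- dv[, 1]
    # e1071 orients the decision value toward the class named first in the
    # column label; flip so positive scores always mean "positive"
    if (!startsWith(colnames(dv)[1], "positive")) s <- -s
    unname(s)
  } else if (alg == "random_forest") {
    unname(stats::predict(object$fit, newdata, type = "prob")[, "positive"]) - 0.5
  } else if (alg == "decision_tree") {
    df <- data.frame(newdata, check.names = TRUE)
    unname(stats::predict(object$fit, df, type = "prob")[, "positive"]) - 0.5
  } else {
    kept <- attr(object$fit, "kept_features")
    unname(stats::predict(object$fit, newdata[, kept, drop = FALSE],
                          type = "raw")[, "positive"]) - 0.5
  }
}

#' @export
print.npp_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("feature scheme: %s (%d features)\n",
              if (is.null(x$feature_scheme)) "<unset>" else x$feature_scheme,
              length(x$feature_names)))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' The default SVM grid is log-spaced kernel widths
#' \code{g in \{1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2, 0.1, 0.5, 1, 5, 10\}},
#' costs \code{c in 1..15} and cost factors \code{j in 1..5}.
#'
#' @param algorithm Learner name as in [model_spec()].
#' @return data.frame with one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm = "svm_rbf") {
  switch(algorithm,
    svm_rbf = expand.grid(
      g = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2, 0.1, 0.5, 1, 5, 10),
      c = 1:15, j = 1:5),
    linear_margin = expand.grid(c = 1:15, j = 1:5),
    random_forest = data.frame(ntree = c(10, 20, 30, 40, 50, 60, 70, 100)),
    decision_tree = expand.grid(c = c(0.001, 0.005, 0.01, 0.05, 0.1),
                                m = c(2, 4, 7, 10)),
    naive_bayes = data.frame(row.names = 1),
    stop("unknown algorithm: ", algorithm))
}

#' Grid search by five-fold cross-validation
#'
#' Evaluates every grid point with [cross_validate()] over the supplied fold
#' assignment and selects the point with the highest mean CV accuracy; ties
#' are broken by higher mean MCC, then by smaller \code{c} (when the grid
#' has a \code{c} column).
#'
#' @param x Feature matrix.
#' @param labels Labels aligned with rows.
#' @param algorithm Learner name.
#' @param grid data.frame of hyperparameter combinations; defaults to
#'   [default_grid()].
#' @param folds Fold assignment aligned with rows.
#' @param seed Integer seed.
#' @return Object of class \code{"npp_grid"}: list with \code{best_spec},
#'   \code{best_cv} (the winning \code{npp_cv}) and \code{summary}
#'   (data.frame of per-point mean accuracy/MCC/AUROC).
#' @export
grid_search <- function(x, labels, algorithm = "svm_rbf",
                        grid = default_grid(algorithm), folds, seed = 1) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  cvs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- do.call(model_spec, c(list(algorithm = algorithm),
                                  as.list(grid[i, , drop = FALSE])))
    cvs[[i]] <- cross_validate(x, labels, folds, spec, seed = seed)
  }
  summ <- cbind(grid,
                acc = vapply(cvs, function(z) z$mean[["acc"]], 0),
                mcc = vapply(cvs, function(z) z$mean[["mcc"]], 0),
                auroc = vapply(cvs, function(z) z$mean[["auroc"]], 0))
  best <- which(summ$acc == max(summ$acc))
  if (length(best) > 1) best <- best[summ$mcc[best] == max(summ$mcc[best])]
  if (length(best) > 1 && "c" %in% names(grid)) {
    best <- best[summ$c[best] == min(summ$c[best])]
  }
  best <- best[1]
  structure(list(best_spec = cvs[[best]]$spec, best_cv = cvs[[best]],
                 summary = summ),
            class = "npp_grid")
}

#' @export
print.npp_grid <- function(x, ...) {
  cat(sprintf("grid search over %d point(s); best:\n", nrow(x$summary)))
  print(x$best_spec)
  print(x$best_cv)
  invisible(x)
}

#' Save or load a trained model
#'
#' The model file embeds a JSON manifest (algorithm, hyperparameters,
#' feature scheme, seed, package version) that [load_model()] validates, so
#' a model cannot silently be applied under the wrong feature scheme.
#'
#' @param model An \code{npp_model}.
#' @param path File path.
#' @return \code{path} invisibly for \code{save_model}; the model for
#'   \code{load_model}.
#' @export
save_model <- function(model, path) {
  manifest <- jsonlite::toJSON(list(
    algorithm = model$spec$algorithm,
    hyperparameters = model$spec$hyperparameters,
    feature_scheme = model$feature_scheme,
    seed = model$seed,
    package = as.character(utils::packageVersion("neuropeptidr"))),
    auto_unbox = TRUE)
  saveRDS(list(manifest = as.character(manifest), model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$manifest) ||
      !inherits(obj$model, "npp_model")) {
    stop("not a model file: ", path)
  }
  man <- jsonlite::fromJSON(obj$manifest)
  if (!identical(man$algorithm, obj$model$spec$algorithm)) {
    stop("model file manifest does not match its payload")
  }
  obj$model
}

#' @rdname save_model
#' @export
model_manifest <- function(model) {
  list(algorithm = model$spec$algorithm,
       hyperparameters = model$spec$hyperparameters,
       feature_scheme = model$feature_scheme,
       seed = model$seed)
}
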