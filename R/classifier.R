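#' Hyperparameter specification for the TES classifier
#'
#' Defaults are the grid-search winners for the gradient-boosted subtype
#' classifier: learning rate 0.1, 100 trees, depth 3, column subsampling
#' 0.8, binary logistic objective, seed 123, evaluated by 10-fold
#' cross-validation. Untuned parameters stay at the library defaults.
#'
#' @param learning_rate Shrinkage per boosting round.
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param colsample_bytree Fraction of features sampled per tree.
#' @param random_state Seed for fold assignment and tree construction.
#' @param cv_folds Number of stratified cross-validation folds.
#' @return A `classifier_spec` list.
#' @export
tes_classifier_spec <- function(learning_rate = 0.1, n_estimators = 100,
                                max_depth = 3, colsample_bytree = 0.8,
                                random_state = 123, cv_folds = 10) {
  stopifnot(learning_rate > 0, n_estimators > 0, max_depth > 0,
            colsample_bytree > 0, colsample_bytree <= 1, cv_folds >= 2)
  structure(list(learning_rate = learning_rate,
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 colsample_bytree = colsample_bytree,
                 objective = "binary:logistic",
                 random_state = as.integer(random_state),
                 cv_folds = as.integer(cv_folds)),
            class = "classifier_spec")
}

xgb_params <- function(spec) {
  list(objective = spec$objective,
       eta = spec$learning_rate,
       max_depth = spec$max_depth,
       colsample_bytree = spec$colsample_bytree,
       nthread = 1L,
       seed = spec$random_state)
}

fit_xgb <- function(x, y, spec) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  xgboost::xgb.train(params = xgb_params(spec), data = dtrain,
                     nrounds = spec$n_estimators, verbose = 0)
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the TES classifier with stratified cross-validation
#'
#' Evaluates the gradient-boosted classifier by stratified k-fold
#' cross-validation on NES features (reporting both the mean of per-fold
#' accuracies and the pooled held-out accuracy, a pooled confusion matrix
#' and ROC AUC), then refits on all samples. Deterministic under the spec's
#' `random_state`.
#'
#' @param features Samples x gene-sets NES matrix with column names.
#' @param labels Two-level subtype label per sample (e.g. 1/2).
#' @param spec A [tes_classifier_spec()].
#' @return Object of class `tes_classifier`: the refit model, the feature
#'   name manifest, class levels, training data (kept for attribution) and
#'   an evaluation `report` (fold accuracies, `cv_accuracy_mean`,
#'   `cv_accuracy_pooled`, `confusion`, `auc`).
#' @export
train_cv <- function(features, labels, spec = tes_classifier_spec()) {
  stopifnot(is.matrix(features), !is.null(colnames(features)),
            nrow(features) == length(labels))
  g <- factor(labels)
  if (nlevels(g) != 2L) {
    stop("the TES classifier is binary; got ", nlevels(g), " classes",
         call. = FALSE)
  }
  if (any(table(g) < spec$cv_folds)) {
    stop("each class needs at least cv_folds = ", spec$cv_folds,
         " samples for stratified cross-validation", call. = FALSE)
  }
  y <- as.integer(g) - 1L
  fold <- stratified_folds(y, spec$cv_folds, spec$random_state)
  prob <- numeric(length(y))
  fold_acc <- numeric(spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- fold != f
    m <- fit_xgb(features[tr, , drop = FALSE], y[tr], spec)
    p <- predict(m, features[!tr, , drop = FALSE])
    prob[!tr] <- p
    fold_acc[f] <- mean((p > 0.5) == y[!tr])
  }
  pred <- as.integer(prob > 0.5)
  confusion <- table(truth = levels(g)[y + 1L],
                     predicted = levels(g)[pred + 1L])
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                        quiet = TRUE, direction = "<",
                                        levels = c(0, 1))))
  model <- fit_xgb(features, y, spec)
  structure(list(model = model,
                 feature_names = colnames(features),
                 classes = levels(g),
                 spec = spec,
                 training_features = features,
                 report = list(fold_accuracies = fold_acc,
                               cv_accuracy_mean = mean(fold_acc),
                               cv_accuracy_pooled = mean(pred == y),
                               confusion = confusion,
                               auc = auc)),
            class = "tes_classifier")
}

#' @export
print.tes_classifier <- function(x, ...) {
  r <- x$report
  cat("tes_classifier:", length(x$feature_names), "features;",
      x$spec$cv_folds, "fold CV accuracy (mean)",
      sprintf("%.4f", r$cv_accuracy_mean),
      "(pooled)", sprintf("%.4f", r$cv_accuracy_pooled),
      "; AUC", sprintf("%.4f", r$auc), "\n")
  invisible(x)
}

#' Predict TES labels for new samples
#'
#' Features are aligned by name, so column order is irrelevant; missing or
#' extra features are an error listing the mismatch.
#'
#' @param object A fitted `tes_classifier`.
#' @param newdata Samples x gene-sets NES matrix with column names.
#' @param ... Unused.
#' @return Data frame with `sample`, `label` (class level) and
#'   `probability` (of the second class level).
#' @export
predict.tes_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list("sample_1", names(newdata)))
  }
  stopifnot(!is.null(colnames(newdata)))
  missing <- setdiff(object$feature_names, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature mismatch; missing: {",
         paste(missing, collapse = ", "), "}, extra: {",
         paste(extra, collapse = ", "), "}", call. = FALSE)
  }
  x <- newdata[, object$feature_names, drop = FALSE]
  prob <- predict(object$model, x)
  data.frame(sample = rownames(x) %||% paste0("sample_", seq_len(nrow(x))),
             label = object$classes[(prob > 0.5) + 1L],
             probability = prob,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank features by mean absolute SHAP attribution
#'
#' Uses the tree-model SHAP decomposition (per-prediction additive feature
#' contributions) on the training samples; features constant across samples
#' receive exactly zero.
#'
#' @param object A fitted `tes_classifier`.
#' @param features Optional samples x features matrix to attribute over;
#'   defaults to the training features.
#' @param top_n Optional number of top rows to return.
#' @return Data frame `feature`, `mean_abs_shap`, sorted descending.
#' @export
feature_importance <- function(object, features = NULL, top_n = NULL) {
  stopifnot(inherits(object, "tes_classifier"))
  x <- features %||% object$training_features
  x <- x[, object$feature_names, drop = FALSE]
  contrib <- predict(object$model, x, predcontrib = TRUE)
  contrib <- contrib[, object$feature_names, drop = FALSE]  # drop bias term
  imp <- colMeans(abs(contrib))
  out <- data.frame(feature = names(imp), mean_abs_shap = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_shap, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}
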