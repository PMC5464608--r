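#' Fit a nested SVM voting ensemble
#'
#' The central classifier: given N ranked features, fits N polynomial-kernel
#' support vector machines where model i uses only the top-i ranked
#' features. At prediction time each model casts an unweighted vote and the
#' class probability is the fraction of votes for disease.
#'
#' Features are standardized to zero mean and unit variance with parameters
#' estimated on the training data only.
#'
#' @param features samples x features numeric matrix.
#' @param labels class labels aligned with rows.
#' @param ranked_ids ordered feature ids (best first), e.g. from
#'   [rank_for_ensemble()]; defaults to the feature table's column order.
#' @param degree,cost,coef0 polynomial kernel hyperparameters (defaults 3,
#'   1, 1).
#' @param seed seed (SVM fitting is deterministic; the seed fixes any
#'   incidental randomness).
#' @return an object of class `icap_ensemble`.
#' @seealso [predict.icap_ensemble()]
#' @export
icap_ensemble <- function(features, labels, ranked_ids = colnames(features),
                          degree = 3, cost = 1, coef0 = 1, seed = 1L) {
  stopifnot(is.matrix(features))
  if (!length(ranked_ids)) stop("ranked_ids is empty")
  missing <- setdiff(ranked_ids, colnames(features))
  if (length(missing)) stop("features missing from table: ",
                            paste(missing, collapse = ", "))
  y <- as_binary_factor(labels)
  if (nlevels(y) != 2) stop("both classes must be present")

  x <- features[, ranked_ids, drop = FALSE]
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center, scl)

  set.seed(child_seed(seed, 51L))
  models <- vector("list", length(ranked_ids))
  for (i in seq_along(ranked_ids)) {
    fit <- try(e1071::svm(xs[, seq_len(i), drop = FALSE], y,
                          kernel = "polynomial", degree = degree,
                          cost = cost, coef0 = coef0, scale = FALSE),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      stop(sprintf("SVM failed for the top-%d feature prefix (%s)", i,
                   paste(ranked_ids[seq_len(i)], collapse = ", ")))
    models[[i]] <- fit
  }
  structure(list(feature_ids = ranked_ids, models = models,
                 center = center, scale = scl, levels = levels(y),
                 kernel = list(degree = degree, cost = cost, coef0 = coef0)),
            class = "icap_ensemble")
}

#' @export
print.icap_ensemble <- function(x, ...) {
  cat(sprintf("Nested SVM voting ensemble: N = %d polynomial-kernel models (degree %g, cost %g)\n",
              length(x$models), x$kernel$degree, x$kernel$cost))
  cat("  top features:",
      paste(utils::head(x$feature_ids, 5), collapse = ", "),
      if (length(x$feature_ids) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.icap_ensemble <- function(object, ...) {
  nsv <- vapply(object$models, function(m) m$tot.nSV, numeric(1))
  cat(sprintf("icap_ensemble with %d nested models\n", length(object$models)))
  cat(sprintf("  support vectors per model: median %g (range %g-%g)\n",
              stats::median(nsv), min(nsv), max(nsv)))
  cat("  positive (disease) class:", object$levels[2], "\n")
  invisible(object)
}

#' @export
coef.icap_ensemble <- function(object, ...) object$feature_ids

# Signed decision value for the disease class from an e1071 svm fit.
svm_decision <- function(fit, newx, positive) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 orients the decision value toward the first label in its colname
  toward <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (toward == positive) dv[, 1] else -dv[, 1]
}

#' Predict with a nested voting ensemble
#'
#' Each of the N models votes; probability = votes / N; the label is disease
#' when the probability exceeds 0.5. An exact 0.5 tie is resolved by the
#' decision value of the model using all N features.
#'
#' @param object an [icap_ensemble()].
#' @param features samples x features matrix containing the model's features.
#' @param ... unused.
#' @return object of class `icap_prediction`: data.frame with `sample_id`,
#'   `votes`, `probability`, `label`, plus matrix `decision_values`
#'   (samples x models).
#' @export
predict.icap_ensemble <- function(object, features, ...) {
  missing <- setdiff(object$feature_ids, colnames(features))
  if (length(missing)) stop("missing feature(s): ",
                            paste(missing, collapse = ", "))
  xs <- scale(features[, object$feature_ids, drop = FALSE],
              object$center, object$scale)
  n <- nrow(xs); N <- length(object$models)
  positive <- object$levels[2]
  dv <- matrix(NA_real_, n, N, dimnames = list(rownames(xs), NULL))
  for (i in seq_len(N))
    dv[, i] <- svm_decision(object$models[[i]],
                            xs[, seq_len(i), drop = FALSE], positive)
  votes <- rowSums(dv > 0)
  prob <- votes / N
  label <- ifelse(prob > 0.5, object$levels[2], object$levels[1])
  tie <- prob == 0.5
  label[tie] <- ifelse(dv[tie, N] > 0, object$levels[2], object$levels[1])
  structure(list(table = data.frame(sample_id = rownames(xs), votes = votes,
                                    probability = prob, label = label,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 decision_values = dv, levels = object$levels,
                 N = N), class = "icap_prediction")
}

#' @export
print.icap_prediction <- function(x, ...) {
  cat(sprintf("Ensemble predictions for %d sample(s) (N = %d voters)\n",
              nrow(x$table), x$N))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tune and fit a single polynomial-kernel SVM
#'
#' Chooses cost and degree by stratified k-fold cross-validation maximizing
#' the area under the ROC curve of the held-out decision values, over a small
#' grid, then refits on all training data.
#'
#' @param features samples x features matrix.
#' @param labels class labels.
#' @param fold_count CV folds (default 10).
#' @param cost_grid,degree_grid hyperparameter grids.
#' @param seed fold-assignment seed.
#' @return object of class `icap_svm` with the chosen hyperparameters, the
#'   CV AUC per grid point, and the refit model.
#' @export
train_tuned_svm <- function(features, labels, fold_count = 10,
                            cost_grid = c(0.1, 1, 10),
                            degree_grid = c(1, 2, 3), seed = 1L) {
  y <- as_binary_factor(labels)
  if (nlevels(y) != 2) stop("both classes must be present")
  if (nrow(features) < fold_count) stop("fewer samples than folds")
  folds <- stratified_folds(y, fold_count, child_seed(seed, 61L))
  center <- colMeans(features)
  scl <- apply(features, 2, stats::sd); scl[scl == 0] <- 1
  positive <- levels(y)[2]

  grid <- expand.grid(cost = cost_grid, degree = degree_grid)
  grid$auc <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    dv <- rep(NA_real_, length(y))
    for (f in unique(folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) stop("single-class training fold")
      xs_tr <- scale(features[tr, , drop = FALSE], center, scl)
      fit <- e1071::svm(xs_tr, y[tr], kernel = "polynomial",
                        degree = grid$degree[gi], cost = grid$cost[gi],
                        coef0 = 1, scale = FALSE)
      xs_te <- scale(features[!tr, , drop = FALSE], center, scl)
      dv[!tr] <- svm_decision(fit, xs_te, positive)
    }
    grid$auc[gi] <- auc_pairwise(dv, y == positive)
  }
  best <- grid[order(-grid$auc, grid$cost, grid$degree)[1], ]
  xs <- scale(features, center, scl)
  fit <- e1071::svm(xs, y, kernel = "polynomial", degree = best$degree,
                    cost = best$cost, coef0 = 1, scale = FALSE)
  structure(list(model = fit, center = center, scale = scl,
                 levels = levels(y), cost = best$cost, degree = best$degree,
                 cv_grid = grid), class = "icap_svm")
}

#' @export
print.icap_svm <- function(x, ...) {
  cat(sprintf("Tuned polynomial SVM: degree %g, cost %g (CV AUC %.3f)\n",
              x$degree, x$cost, max(x$cv_grid$auc)))
  invisible(x)
}

#' @export
predict.icap_svm <- function(object, features, type = c("label", "decision"),
                             ...) {
  type <- match.arg(type)
  xs <- scale(features[, names(object$center), drop = FALSE],
              object$center, object$scale)
  dv <- svm_decision(object$model, xs, object$levels[2])
  if (type == "decision") return(dv)
  ifelse(dv > 0, object$levels[2], object$levels[1])
}

# Stratified fold assignment, roughly equal class proportions per fold.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Tie-corrected pairwise AUC (Mann-Whitney with ties counted 0.5).
auc_pairwise <- function(score, positive) {
  s1 <- score[positive]; s0 <- score[!positive]
  if (!length(s1) || !length(s0)) return(NA_real_)
  cmp <- outer(s1, s0, `>`) + 0.5 * outer(s1, s0, `==`)
  mean(cmp)
}

#' Fuse a clinical covariate into a feature table
#'
#' Appends one numeric covariate column (by default the APOE4 allele count)
#' to a feature table, or builds a covariate-only single-feature table.
#'
#' @param features samples x features matrix, or `NULL` for covariate-only
#'   mode.
#' @param meta sample metadata containing the covariate.
#' @param covariate metadata column name (default `"apoe4_count"`).
#' @param samples sample ids (rows) when `features` is `NULL`.
#' @return the augmented (or single-column) feature matrix.
#' @export
fuse_covariate <- function(features, meta, covariate = "apoe4_count",
                           samples = rownames(features)) {
  if (!covariate %in% colnames(meta)) stop("covariate not in metadata")
  vals <- stats::setNames(meta[[covariate]], meta$sample_id)[samples]
  if (anyNA(vals))
    stop("missing covariate values for sample(s): ",
         paste(samples[is.na(vals)], collapse = ", "))
  if (is.null(features))
    return(matrix(vals, ncol = 1, dimnames = list(samples, covariate)))
  if (covariate %in% colnames(features))
    stop("duplicate feature id: ", covariate)
  cbind(features, matrix(vals, ncol = 1,
                         dimnames = list(samples, covariate)))
}
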