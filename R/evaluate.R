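#' Binary confusion metrics
#'
#' Computes the full metric panel for a binary prediction table with disease
#' as the positive class: TP/FP/TN/FN, accuracy, sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), false positive rate FP/(TN+FP), prediction false
#' discovery rate FP/(TP+FP), F1 = 2TP/(2TP+FP+FN), and the Matthews
#' correlation coefficient. Cells whose denominator is zero are reported as
#' `NA` (undefined), never coerced to 0. The exact binomial tail p-value of
#' the accuracy and the t-distribution p-value of the MCC are attached.
#'
#' @param predicted,actual aligned label vectors (mapped via [is_disease()],
#'   or logical disease indicators).
#' @return object of class `confusion_metrics`.
#' @export
confusion_metrics <- function(predicted, actual) {
  pd <- to_disease(predicted)
  ad <- to_disease(actual)
  stopifnot(length(pd) == length(ad))
  if (anyNA(pd) || anyNA(ad)) stop("labels must be binary, no unknowns")
  tp <- sum(pd & ad); fp <- sum(pd & !ad)
  tn <- sum(!pd & !ad); fn <- sum(!pd & ad)
  n <- tp + fp + tn + fn
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  out <- list(TP = tp, FP = fp, TN = tn, FN = fn, n = n,
              accuracy = div(tp + tn, n),
              sensitivity = div(tp, tp + fn),
              specificity = div(tn, tn + fp),
              fpr = div(fp, tn + fp),
              fdr = div(fp, tp + fp),
              f1 = div(2 * tp, 2 * tp + fp + fn),
              mcc = mcc,
              binomial_p = binomial_pvalue_strict(tp + tn, n),
              mcc_p = if (is.na(mcc) || n < 4) NA_real_
                      else as.numeric(mcc_pvalue_t(mcc, n)))
  class(out) <- "confusion_metrics"
  out
}

to_disease <- function(x) {
  if (is.logical(x)) return(x)
  is_disease(as.character(x))
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion metrics (n = %d): TP %d FP %d TN %d FN %d\n",
              x$n, x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy %.3f (binomial p = %.3g), sens %.3f, spec %.3f\n",
              x$accuracy, x$binomial_p, x$sensitivity, x$specificity))
  cat(sprintf("  FPR %.3f, FDR %.3f, F1 %.3f, MCC %.3f (p = %.3g)\n",
              x$fpr, x$fdr, x$f1, x$mcc, x$mcc_p))
  invisible(x)
}

#' Exact binomial tail p-value, strictly-greater convention
#'
#' P(X > k) for X ~ Binomial(n, p0): the probability of MORE than the
#' observed number of correct calls under chance. This strictly-greater
#' convention reproduces the published classifier p-values (e.g. 10/12
#' correct gives 13/4096 = 3.17E-3). Note k = n yields 0 under this
#' convention; the textbook P(X >= k) tail is available via
#' `convention = "geq"`.
#'
#' @param k number of correct calls.
#' @param n number of calls.
#' @param p0 chance success probability (default 0.5).
#' @param convention `"greater"` (default) or `"geq"`.
#' @return the tail probability.
#' @export
binomial_pvalue_strict <- function(k, n, p0 = 0.5,
                                   convention = c("greater", "geq")) {
  convention <- match.arg(convention)
  stopifnot(k >= 0, k <= n)
  lo <- if (convention == "greater") k + 1 else k
  if (lo > n) return(0)
  sum(stats::dbinom(lo:n, n, p0))
}

#' Significance of a Matthews correlation coefficient
#'
#' Default method treats the MCC as a Pearson correlation over n paired
#' calls and applies the correlation t-test: t = mcc * sqrt((n-2)/(1-mcc^2))
#' with n - 2 degrees of freedom, two-sided. This convention reproduces the
#' published MCC p-values. A Fisher z-transform alternative is available via
#' `method = "fisher_z"`.
#'
#' @param mcc the coefficient, |mcc| <= 1.
#' @param n number of predictions (>= 4).
#' @param method `"t"` (default) or `"fisher_z"`.
#' @return two-sided p-value. `|mcc| = 1` returns the degrees-of-freedom
#'   limit 0 with attribute `degenerate = TRUE`.
#' @export
mcc_pvalue_t <- function(mcc, n, method = c("t", "fisher_z")) {
  method <- match.arg(method)
  stopifnot(abs(mcc) <= 1, n >= 4)
  if (abs(mcc) == 1)
    return(structure(0, degenerate = TRUE))
  if (method == "t") {
    t <- mcc * sqrt((n - 2) / (1 - mcc^2))
    2 * stats::pt(-abs(t), df = n - 2)
  } else {
    z <- atanh(mcc) * sqrt(n - 3)
    2 * stats::pnorm(-abs(z))
  }
}

#' ROC curve over ensemble vote thresholds
#'
#' Sweeps the number of votes required to call disease from 0 to N + 1 and
#' reports the ROC points and trapezoidal AUC, which equals the
#' Mann-Whitney pairwise statistic with ties counted 0.5.
#'
#' @param votes per-sample disease vote counts (0..N).
#' @param actual true labels.
#' @param N ensemble size (defaults to `max(votes)`).
#' @return list with `auc` and data.frame `curve` (`threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc_votes <- function(votes, actual, N = max(votes)) {
  ad <- to_disease(actual)
  if (length(unique(ad)) < 2) {
    warning("single-class truth; AUC undefined")
    return(list(auc = NA_real_, curve = NULL))
  }
  stopifnot(all(votes >= 0 & votes <= N))
  thr <- 0:(N + 1)
  tpr <- vapply(thr, function(t) mean(votes[ad] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(votes[!ad] >= t), numeric(1))
  ord <- order(fpr, tpr)
  fx <- fpr[ord]; ty <- tpr[ord]
  auc <- sum(diff(fx) * (utils::head(ty, -1) + utils::tail(ty, -1)) / 2)
  list(auc = auc, curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment over the m supplied tests (a thin wrapper
#' over [stats::p.adjust()] keeping input order).
#'
#' @param p p-values in [0, 1].
#' @param m number of tests (defaults to `length(p)`).
#' @return q-values aligned with `p`.
#' @export
bh_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH", n = m)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing at least the given overlap between a
#' hit list and an annotation set drawn from a finite universe.
#'
#' @param n_hits size of the hit list.
#' @param n_annotation size of the annotation set.
#' @param n_overlap observed overlap.
#' @param n_universe universe size.
#' @return p-value.
#' @export
hypergeom_enrichment <- function(n_hits, n_annotation, n_overlap,
                                 n_universe) {
  stopifnot(n_universe > 0, n_hits <= n_universe,
            n_annotation <= n_universe, n_overlap <= min(n_hits, n_annotation))
  stats::phyper(n_overlap - 1, n_annotation, n_universe - n_annotation,
                n_hits, lower.tail = FALSE)
}

#' Cross-validation harness with in-fold feature selection
#'
#' Runs a user-supplied training pipeline under leave-one-out or repeated
#' stratified k-fold cross-validation. The pipeline is called on each
#' training fold only — every feature-selection and tuning step that sees
#' disease status happens inside the fold — and must return a list with a
#' `predict(newx)` function (returning labels) and optionally `features`
#' (the selected feature ids, logged per training set) and
#' `probability(newx)`.
#'
#' @param features samples x features matrix (the rawest representation the
#'   pipeline needs).
#' @param labels class labels.
#' @param pipeline function(train_features, train_labels, seed) -> list as
#'   described above.
#' @param mode `"loocv"` or `"repeated_kfold"`.
#' @param k folds for repeated k-fold.
#' @param n_reps repetitions for repeated k-fold.
#' @param seed base seed.
#' @return object of class `cv_result`: `predictions` (pooled data.frame
#'   with `sample_id`, `repetition`, `predicted`, `actual`), `pooled`
#'   ([confusion_metrics()] over all predictions), `per_rep` (metric
#'   data.frame per repetition), `selection_log` (list of selected feature
#'   vectors, one per trained model).
#' @export
cv_harness <- function(features, labels, pipeline,
                       mode = c("loocv", "repeated_kfold"), k = 16,
                       n_reps = 100, seed = 1L) {
  mode <- match.arg(mode)
  y <- as_binary_factor(labels)
  n <- nrow(features)
  reps <- if (mode == "loocv") 1L else n_reps
  preds <- NULL
  selection_log <- list()
  for (r in seq_len(reps)) {
    folds <- if (mode == "loocv") seq_len(n)
             else stratified_folds(y, k, child_seed(seed, 100L + r))
    predicted <- rep(NA_character_, n)
    for (f in unique(folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) stop("single-class training fold")
      fit <- pipeline(features[tr, , drop = FALSE], labels[tr],
                      seed = child_seed(seed, 1000L * r + f))
      predicted[!tr] <- fit$predict(features[!tr, , drop = FALSE])
      selection_log[[length(selection_log) + 1L]] <-
        if (!is.null(fit$features)) fit$features else character()
    }
    preds <- rbind(preds, data.frame(
      sample_id = rownames(features), repetition = r,
      predicted = predicted, actual = as.character(labels),
      stringsAsFactors = FALSE))
  }
  per_rep <- do.call(rbind, lapply(split(preds, preds$repetition),
    function(d) {
      cm <- confusion_metrics(d$predicted, d$actual)
      data.frame(repetition = d$repetition[1], accuracy = cm$accuracy,
                 mcc = cm$mcc, sensitivity = cm$sensitivity,
                 specificity = cm$specificity)
    }))
  rownames(per_rep) <- NULL
  structure(list(predictions = preds,
                 pooled = confusion_metrics(preds$predicted, preds$actual),
                 per_rep = per_rep, selection_log = selection_log,
                 mode = mode), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation (%s): %d repetition(s), %d trained model(s)\n",
              x$mode, nrow(x$per_rep), length(x$selection_log)))
  cat(sprintf("  pooled accuracy %.3f, MCC %.3f\n",
              x$pooled$accuracy, x$pooled$mcc))
  invisible(x)
}

#' Paired comparison of two cross-validated classifiers
#'
#' Two-sided Wilcoxon signed-rank test on a per-repetition metric.
#'
#' @param cv_a,cv_b `cv_result` objects from repeated k-fold runs with the
#'   same repetitions.
#' @param metric column of `per_rep` to compare.
#' @return the `htest` from [stats::wilcox.test()].
#' @export
compare_cv <- function(cv_a, cv_b, metric = "accuracy") {
  stopifnot(nrow(cv_a$per_rep) == nrow(cv_b$per_rep))
  stats::wilcox.test(cv_a$per_rep[[metric]], cv_b$per_rep[[metric]],
                     paired = TRUE, exact = FALSE)
}

#' Feature-selection stability
#'
#' Features selected in at least a threshold fraction of the logged training
#' sets.
#'
#' @param selection_log list of character vectors (e.g.
#'   `cv_result$selection_log`).
#' @param threshold fraction (default 0.5).
#' @return character vector of stable feature ids.
#' @export
feature_stability <- function(selection_log, threshold = 0.5) {
  if (!length(selection_log)) stop("empty selection log")
  counts <- table(unlist(selection_log, use.names = FALSE))
  names(counts)[counts / length(selection_log) >= threshold]
}
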