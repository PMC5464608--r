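#' Fit a Laplacian residual model for class probabilities
#'
#' Fits a single polynomial-kernel SVM under 3-fold cross-validation, takes
#' the held-out decision values, and forms residuals against the +/-1 class
#' encoding (+1 disease). The residual distribution is summarized by a
#' Laplacian with location = median and scale = mean absolute deviation from
#' the location; a zero scale is floored at machine tolerance with a
#' warning.
#'
#' @param features samples x features matrix (labeled training data).
#' @param labels class labels.
#' @param degree,cost,coef0 kernel hyperparameters for the probability SVM.
#' @param seed fold seed.
#' @return object of class `residual_laplace` with `location`, `scale` and
#'   the refit full-data SVM.
#' @export
fit_residual_laplace <- function(features, labels, degree = 3, cost = 1,
                                 coef0 = 1, seed = 1L) {
  y <- as_binary_factor(labels)
  if (length(y) < 6) stop("need at least 6 labeled samples")
  folds <- stratified_folds(y, 3L, child_seed(seed, 71L))
  center <- colMeans(features)
  scl <- apply(features, 2, stats::sd); scl[scl == 0] <- 1
  positive <- levels(y)[2]
  dv <- rep(NA_real_, length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    xs_tr <- scale(features[tr, , drop = FALSE], center, scl)
    fit <- e1071::svm(xs_tr, y[tr], kernel = "polynomial", degree = degree,
                      cost = cost, coef0 = coef0, scale = FALSE)
    xs_te <- scale(features[!tr, , drop = FALSE], center, scl)
    dv[!tr] <- svm_decision(fit, xs_te, positive)
  }
  enc <- ifelse(y == positive, 1, -1)
  resid <- enc - dv
  res <- laplace_fit(resid)
  xs <- scale(features, center, scl)
  full <- e1071::svm(xs, y, kernel = "polynomial", degree = degree,
                     cost = cost, coef0 = coef0, scale = FALSE)
  structure(list(location = res$location, scale = res$scale,
                 model = full, center = center, feat_scale = scl,
                 levels = levels(y)), class = "residual_laplace")
}

# location = median, scale = mean |x - location|; floored when degenerate.
laplace_fit <- function(x) {
  loc <- stats::median(x)
  b <- mean(abs(x - loc))
  if (b <= 0) {
    warning("zero residual scale; flooring at machine tolerance")
    b <- .Machine$double.eps
  }
  list(location = loc, scale = b)
}

laplace_cdf <- function(q, location, scale) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

#' @export
print.residual_laplace <- function(x, ...) {
  cat(sprintf("Laplacian residual model: location %.4g, scale %.4g\n",
              x$location, x$scale))
  invisible(x)
}

binary_entropy <- function(p) {
  term <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Score unlabeled candidates by predictive entropy
#'
#' For each unlabeled sample the SVM decision value d is converted to
#' p(disease) = 1 - F(-d) with F the fitted Laplacian CDF, and the entropy
#' of the implied class distribution is computed in bits. A tie-break
#' entropy from the voting ensemble's class probability is attached when an
#' ensemble is supplied.
#'
#' @param rm a [fit_residual_laplace()] model.
#' @param unlabeled samples x features matrix.
#' @param ensemble optionally an [icap_ensemble()] for tie-break entropies.
#' @return data.frame `sample_id`, `decision`, `probability`, `entropy`,
#'   `tie_entropy` sorted as supplied.
#' @export
candidate_entropies <- function(rm, unlabeled, ensemble = NULL) {
  xs <- scale(unlabeled[, names(rm$center), drop = FALSE],
              rm$center, rm$feat_scale)
  d <- svm_decision(rm$model, xs, rm$levels[2])
  p <- 1 - laplace_cdf(-d, rm$location, rm$scale)
  out <- data.frame(sample_id = rownames(unlabeled), decision = d,
                    probability = p, entropy = binary_entropy(p),
                    tie_entropy = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(ensemble)) {
    pr <- predict(ensemble, unlabeled)
    out$tie_entropy <- binary_entropy(pr$table$probability)
  }
  out
}

#' Minimum-entropy active-learning loop
#'
#' Replays the blinded-test protocol: at each iteration all remaining
#' unlabeled samples are scored, the sample with minimum entropy is chosen
#' (ties broken by the ensemble's entropy, then by id order), its class is
#' predicted and committed to the transcript BEFORE the oracle reveals the
#' true label, and the newly labeled example is appended to the training set
#' before the SVMs are refit on the fixed feature set. The transcript rows
#' are hash-chained so the commit-before-reveal ordering is auditable.
#'
#' @param features samples x features matrix for the labeled training pool.
#' @param labels training class labels.
#' @param unlabeled samples x features matrix of the blinded pool.
#' @param oracle function(sample_id) returning the true label, or a named
#'   vector of sealed labels; returning `NA` halts the loop.
#' @param ranked_ids ordered feature ids for the ensemble (defaults to
#'   column order).
#' @param degree,cost,coef0 kernel hyperparameters.
#' @param seed seed (fold assignment inside the residual fit).
#' @return object of class `active_transcript`: data.frame with `iteration`,
#'   `sample_id`, `probability`, `prediction`, `revealed_label`, `hash`.
#' @export
active_loop <- function(features, labels, unlabeled, oracle,
                        ranked_ids = colnames(features), degree = 3,
                        cost = 1, coef0 = 1, seed = 1L) {
  if (!is.function(oracle)) {
    sealed <- oracle
    oracle <- function(id) if (id %in% names(sealed)) sealed[[id]] else NA
  }
  transcript <- data.frame(iteration = integer(), sample_id = character(),
                           probability = numeric(), prediction = character(),
                           revealed_label = character(), hash = character(),
                           stringsAsFactors = FALSE)
  chain <- "genesis"
  pool <- unlabeled
  it <- 0L
  while (nrow(pool) > 0) {
    it <- it + 1L
    rm <- fit_residual_laplace(features, labels, degree, cost, coef0,
                               seed = child_seed(seed, it))
    ens <- icap_ensemble(features, labels, ranked_ids, degree, cost, coef0,
                         seed = child_seed(seed, it))
    sc <- candidate_entropies(rm, pool, ens)
    ord <- order(sc$entropy, sc$tie_entropy, sc$sample_id)
    pick <- sc[ord[1], ]
    pr <- predict(ens, pool[pick$sample_id, , drop = FALSE])
    prediction <- pr$table$label[1]
    prob <- pr$table$probability[1]
    # commit the prediction before the label is revealed
    chain <- md5_string(paste(chain, it, pick$sample_id, prob, prediction,
                              sep = "|"))
    revealed <- oracle(pick$sample_id)
    transcript <- rbind(transcript, data.frame(
      iteration = it, sample_id = pick$sample_id, probability = prob,
      prediction = prediction,
      revealed_label = ifelse(is.na(revealed), NA_character_,
                              as.character(revealed)),
      hash = chain, stringsAsFactors = FALSE))
    if (is.na(revealed)) break
    features <- rbind(features, pool[pick$sample_id, , drop = FALSE])
    labels <- c(labels, as.character(revealed))
    pool <- pool[setdiff(rownames(pool), pick$sample_id), , drop = FALSE]
  }
  structure(list(transcript = transcript), class = "active_transcript")
}

#' @export
print.active_transcript <- function(x, ...) {
  cat(sprintf("Active-learning transcript: %d iteration(s)\n",
              nrow(x$transcript)))
  print(x$transcript[, c("iteration", "sample_id", "probability",
                         "prediction", "revealed_label")],
        row.names = FALSE)
  invisible(x)
}
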