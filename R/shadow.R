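#' Shadow-feature family-wise error rates
#'
#' Ranks features against artificially generated random probes. In each
#' repetition every real feature is duplicated as a "shadow" with its values
#' permuted across samples, an importance engine scores real and shadow
#' features together, and a real feature is beaten whenever the best shadow
#' importance reaches its own. FWER(f) is the fraction of repetitions in
#' which any shadow beat f; features are ranked by FWER ascending with ties
#' broken by mean importance descending.
#'
#' Backends: `"forest"` (random forest with `n_trees` trees; importance =
#' mean decrease in impurity) and `"fern"` (a simplified random-fern
#' ensemble; experimental).
#'
#' @param features samples x features numeric matrix.
#' @param labels class labels aligned with rows (coerced via [is_disease()]
#'   when they look like study labels, otherwise used as a 2-level factor).
#' @param backend importance engine.
#' @param n_trees trees per forest (default 1000) or ferns per ensemble.
#' @param n_reps shadow repetitions (>= 20).
#' @param seed integer seed; fixed seed gives identical FWERs.
#' @return object of class `ranked_features`: data.frame with `feature`,
#'   `fwer`, `importance` (mean over repetitions), `rank`.
#' @export
compute_fwer <- function(features, labels, backend = c("forest", "fern"),
                         n_trees = 1000, n_reps = 100, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (n_reps < 20) stop("n_reps must be at least 20")
  y <- as_binary_factor(labels)
  if (nlevels(y) < 2) stop("need two classes")

  const <- apply(features, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(features)[const], collapse = ", "))
    features <- features[, !const, drop = FALSE]
  }
  p <- ncol(features)
  if (p == 0) stop("no usable features")

  beaten <- numeric(p)
  imp_sum <- numeric(p)
  set.seed(child_seed(seed, 41L))
  for (r in seq_len(n_reps)) {
    shadow <- apply(features, 2, sample)
    colnames(shadow) <- paste0(".shadow.", colnames(features))
    x <- cbind(features, shadow)
    imp <- switch(backend,
      forest = forest_importance(x, y, n_trees),
      fern = fern_importance(x, y, n_trees))
    real <- imp[seq_len(p)]
    max_shadow <- max(imp[p + seq_len(p)])
    beaten <- beaten + (max_shadow >= real)
    imp_sum <- imp_sum + real
  }
  tab <- data.frame(feature = colnames(features), fwer = beaten / n_reps,
                    importance = imp_sum / n_reps, stringsAsFactors = FALSE)
  ord <- order(tab$fwer, -tab$importance, tab$feature)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, backend = backend, n_trees = n_trees,
                 n_reps = n_reps), class = "ranked_features")
}

as_binary_factor <- function(labels) {
  if (is.factor(labels)) return(droplevels(labels))
  d <- is_disease(labels)
  if (!any(is.na(d))) return(factor(d, levels = c(FALSE, TRUE),
                                    labels = c("control", "disease")))
  factor(labels)
}

forest_importance <- function(x, y, n_trees) {
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp[colnames(x)]
}

# Simplified random-fern ensemble importance. Each fern draws `depth` random
# features with random data-driven thresholds, partitioning samples into
# 2^depth leaves; its score is the gain of the leaf-wise majority-class
# training accuracy over the base rate, credited equally to the features
# used. Experimental stand-in for a full ferns implementation.
fern_importance <- function(x, y, n_ferns, depth = 3L) {
  p <- ncol(x); n <- nrow(x)
  depth <- min(depth, p)
  base <- max(table(y)) / n
  imp <- stats::setNames(numeric(p), colnames(x))
  for (f in seq_len(n_ferns)) {
    feats <- sample.int(p, depth)
    leaf <- integer(n)
    for (j in seq_along(feats)) {
      v <- x[, feats[j]]
      thr <- v[sample.int(n, 1)]
      leaf <- leaf * 2L + (v > thr)
    }
    acc <- sum(vapply(split(as.integer(y), leaf), function(g)
      max(tabulate(g, nlevels(y))), numeric(1))) / n
    imp[feats] <- imp[feats] + max(acc - base, 0) / depth
  }
  imp
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("Shadow-feature ranking (%s backend, %d reps, %d trees): %d features\n",
              x$backend, x$n_reps, x$n_trees, nrow(x$table)))
  cat(sprintf("  %d with FWER < 1.0\n", sum(x$table$fwer < 1)))
  invisible(x)
}

#' Ordered features for the nested ensemble
#'
#' Features whose shadow FWER is below `cutoff`, in rank order (FWER
#' ascending, ties by mean importance descending). The length of the result
#' is the ensemble size N.
#'
#' @param ranked a [compute_fwer()] result.
#' @param cutoff FWER cutoff (default 1.0, i.e. keep anything that ever beat
#'   its shadows).
#' @return character vector of ordered feature ids.
#' @export
rank_for_ensemble <- function(ranked, cutoff = 1.0) {
  stopifnot(inherits(ranked, "ranked_features"))
  ids <- ranked$table$feature[ranked$table$fwer < cutoff]
  if (!length(ids))
    stop("no feature passes the FWER cutoff; increase n_reps or provide stronger features")
  ids
}
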