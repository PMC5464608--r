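test_that("confusion metrics agree with the brute-force recount everywhere", {
  act <- rep(c(TRUE, FALSE), each = 6)
  for (code in seq_len(2^12) - 1) {
    pred <- as.logical(bitwAnd(bitwShiftR(code, 0:11), 1L))
    cm <- confusion_metrics(pred, act)
    expect_identical(c(cm$TP, cm$FP, cm$TN, cm$FN), naive_confusion(pred, act))
  }
})

test_that("undefined rates are NA rather than zero", {
  cm <- confusion_metrics(rep(FALSE, 4), rep(TRUE, 4))  # no positive calls
  expect_true(is.na(cm$fdr))
  expect_true(is.na(cm$specificity))
  expect_equal(cm$sensitivity, 0)
  cm2 <- confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(cm2$mcc, 1)
  expect_equal(cm2$f1, 1)
  expect_error(confusion_metrics(c("carrier", "unknown"),
                                 c("carrier", "carrier")), "binary")
})

test_that("the strict binomial tail equals direct summation", {
  for (n in c(12, 18, 40, 60)) {
    for (k in c(0, 1, n %/% 2, n - 1, n)) {
      direct <- sum(vapply((k + 1):n, function(j)
        choose(n, j) * 0.5^n, numeric(1)))
      if (k == n) direct <- 0
      expect_equal(binomial_pvalue_strict(k, n), direct, tolerance = 1e-14)
    }
  }
  # textbook convention includes k itself
  expect_equal(binomial_pvalue_strict(12, 12, convention = "geq"),
               0.5^12)
  expect_equal(binomial_pvalue_strict(12, 12), 0)
})

test_that("MCC significance conventions behave at the edges", {
  expect_equal(mcc_pvalue_t(0, 10), 1)
  p <- mcc_pvalue_t(1, 10)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
  # Fisher-z alternative is monotone in |mcc| too
  expect_lt(mcc_pvalue_t(0.9, 20, method = "fisher_z"),
            mcc_pvalue_t(0.5, 20, method = "fisher_z"))
})

test_that("vote-threshold AUC equals the pairwise comparison statistic", {
  # disease votes {3, 2}, control votes {1, 2}: 3.5 of 4 pairs
  votes <- c(3, 2, 1, 2)
  actual <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc_votes(votes, actual, N = 3)$auc, 0.875)
  # perfectly separated votes
  expect_equal(roc_auc_votes(c(5, 5, 0, 0), actual, N = 5)$auc, 1)
  # all votes equal: pure ties
  expect_equal(roc_auc_votes(c(2, 2, 2, 2), actual, N = 4)$auc, 0.5)
  # random vote patterns match the pairwise statistic and pROC
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:10) {
    v <- sample(0:8, 12, replace = TRUE)
    a <- rep(c(TRUE, FALSE), each = 6)
    ours <- roc_auc_votes(v, a, N = 8)$auc
    expect_equal(ours, icapr:::auc_pairwise(v, a), tolerance = 1e-12)
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      a, v, levels = c(FALSE, TRUE), direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_warning(roc_auc_votes(c(1, 2), c(TRUE, TRUE), N = 3), "single-class")
})

test_that("BH adjustment is the step-up procedure", {
  p <- c(2.44e-4, 3.17e-3, 3.17e-3, 1.93e-2, 7.30e-2)
  q <- bh_adjust(p)
  expect_equal(q[1], 1.22e-3, tolerance = 1e-3)
  expect_equal(q[2], 5.28e-3, tolerance = 1e-2)
  expect_equal(q[2], q[3])
  # monotone non-decreasing in sorted p order, bounded by 1
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1))
  expect_equal(bh_adjust(0.03), 0.03)     # single p passes through
})

test_that("hypergeometric enrichment matches the exact count", {
  # universe 10, annotation 5, hits 4, overlap 4
  expect_equal(hypergeom_enrichment(4, 5, 4, 10),
               choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_gt(hypergeom_enrichment(10, 2, 0, 1000), 0.97)  # no overlap, p ~ 1
  expect_equal(hypergeom_enrichment(10, 10, 10, 10), 1)  # everything hits
})

test_that("LOOCV predicts every sample exactly once", {
  d <- separable_features(n = 6, p = 2, gap = 4, seed = 3)
  pipeline <- function(x, lab, seed) {
    ens <- icap_ensemble(x, lab, seed = seed)
    list(predict = function(newx) predict(ens, newx)$table$label,
         features = colnames(x))
  }
  cv <- cv_harness(d$x, d$labels, pipeline, mode = "loocv")
  expect_equal(nrow(cv$predictions), 12)
  expect_setequal(cv$predictions$sample_id, rownames(d$x))
  expect_equal(cv$pooled$accuracy, 1)
  expect_length(cv$selection_log, 12)
})

test_that("repeated k-fold logs one model per fold per repetition", {
  d <- separable_features(n = 8, p = 2, gap = 4, seed = 5)
  pipeline <- function(x, lab, seed) {
    ens <- icap_ensemble(x, lab, ranked_ids = "f1", seed = seed)
    list(predict = function(newx) predict(ens, newx)$table$label,
         features = "f1")
  }
  cv <- cv_harness(d$x, d$labels, pipeline, mode = "repeated_kfold",
                   k = 4, n_reps = 5, seed = 2)
  expect_equal(length(cv$selection_log), 20)      # 5 reps x 4 folds
  expect_equal(nrow(cv$per_rep), 5)
  # every sample predicted exactly once per repetition
  counts <- table(cv$predictions$sample_id, cv$predictions$repetition)
  expect_true(all(counts == 1))
  # paired comparison runs
  cmp <- compare_cv(cv, cv)
  expect_s3_class(cmp, "htest")
})

test_that("feature stability counts selection frequency", {
  logs <- c(replicate(60, c("a", "b"), simplify = FALSE),
            replicate(40, "b", simplify = FALSE))
  expect_setequal(feature_stability(logs, 0.5), c("a", "b"))
  expect_identical(feature_stability(logs, 1.0), "b")
  expect_error(feature_stability(list()), "empty")
})
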