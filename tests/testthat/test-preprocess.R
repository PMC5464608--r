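test_that("exon summarization is the per-gene exon mean", {
  vals <- matrix(c(1, 2, 3, 4,
                   2, 3, 4, 5,
                   3, 4, 5, 6,
                   7, 7, 7, 7), 4, 4, byrow = TRUE,
                 dimnames = list(c("gA_e1", "gA_e2", "gA_e3", "gB_e1"),
                                 paste0("s", 1:4)))
  em <- exon_matrix(vals, c(gA_e1 = "gA", gA_e2 = "gA", gA_e3 = "gA",
                            gB_e1 = "gB"))
  g <- summarize_exons(em)
  expect_equal(unname(g["gA", ]), c(2, 3, 4, 5))
  expect_equal(unname(g["gB", ]), rep(7, 4))     # single-exon identity
  expect_identical(attr(g, "scale"), "log2_intensity")
  # permuting exon rows changes nothing
  perm <- exon_matrix(vals[c(4, 2, 1, 3), ], em$exon_to_gene)
  expect_equal(summarize_exons(perm)[rownames(g), ], g, ignore_attr = TRUE)
  # gene-level input passes through unchanged
  expect_identical(summarize_exons(g), g)
})

test_that("correlation QC removes an anticorrelated array", {
  set.seed(42)
  base <- rnorm(200, mean = 8)
  good <- sapply(1:5, function(i) base + rnorm(200, sd = 0.05))
  bad <- 16 - base + rnorm(200, sd = 0.05)    # anticorrelated
  m <- expr_matrix(cbind(good, bad), "log2_intensity")
  colnames(m) <- paste0("a", 1:6)
  rownames(m) <- paste0("g", 1:200)
  meta <- data.frame(sample_id = paste0("a", 1:6), class = "non-carrier",
                     batch = 1)
  qc <- qc_outliers(m, meta)
  expect_identical(qc$removed_sample_ids, "a6")

  # independent oracle: Grubbs G on the average-r scores vs the two-sided
  # critical value from the t-quantile formula
  r <- cor(m)
  avg <- (rowSums(r) - 1) / 5
  G <- (mean(avg) - min(avg)) / sd(avg)
  n <- 6
  t2 <- qt(1 - 0.05 / (2 * n), n - 2)^2
  crit <- (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
  expect_gt(G, crit)

  # near-identical arrays only: nothing removed
  m2 <- expr_matrix(cbind(good, base + rnorm(200, sd = 0.05)),
                    "log2_intensity")
  dimnames(m2) <- dimnames(m)
  expect_length(qc_outliers(m2, meta)$removed_sample_ids, 0)
})

test_that("QC is robust to degenerate scores and column order", {
  # constant correlations (sd = 0): no removal, no numerical failure
  m <- expr_matrix(matrix(rep(c(1, 2, 3, 4), 4), 4, 4,
                          dimnames = list(paste0("g", 1:4),
                                          paste0("s", 1:4))),
                   "log2_intensity")
  meta <- data.frame(sample_id = paste0("s", 1:4), class = "non-carrier",
                     batch = 1)
  expect_length(qc_outliers(m, meta)$removed_sample_ids, 0)

  # removal decisions invariant to sample column order
  st <- small_study(seed = 9, n_outlier_arrays = 2)
  qc1 <- qc_outliers(st$gene, st$meta)
  shuf <- sample(colnames(st$gene))
  qc2 <- qc_outliers(st$gene[, shuf], st$meta)
  expect_setequal(qc1$removed_sample_ids, qc2$removed_sample_ids)

  # undersized batch skipped with warning
  meta_small <- data.frame(sample_id = paste0("s", 1:4),
                           class = "non-carrier", batch = c(1, 1, 1, 2))
  expect_warning(qc_outliers(m, meta_small), "fewer than 3")
})

test_that("marker model recovers exact and independent targets", {
  set.seed(1)
  n_ref <- 8
  markers <- matrix(rnorm(4 * n_ref, mean = 8), 4, n_ref,
                    dimnames = list(c("Olig2", "Mnx1", "Isl1", "Lhx3"),
                                    paste0("r", 1:n_ref)))
  target_exact <- 2 * markers["Olig2", ]
  target_indep <- rep(5, n_ref) + rnorm(n_ref, sd = 1e-12)
  m <- expr_matrix(rbind(markers, tE = target_exact, tI = target_indep),
                   "log2_intensity")
  meta <- data.frame(sample_id = paste0("r", 1:n_ref),
                     class = "non-carrier", batch = 1)
  mm <- fit_marker_model(m, meta)
  expect_equal(mm$coefficients["Olig2", "tE"], 2, tolerance = 1e-8)
  expect_equal(mm$coefficients["Mnx1", "tE"], 0, tolerance = 1e-8)
  expect_equal(unname(predict(mm, m)["tE", ]), unname(target_exact),
               tolerance = 1e-8)

  # independent target: prediction ~ reference mean; oracle = normal
  # equations computed directly
  X <- cbind(1, t(markers))
  beta <- solve(t(X) %*% X, t(X) %*% cbind(target_indep))
  expect_equal(unname(mm$coefficients[, "tI"]), unname(beta[, 1]),
               tolerance = 1e-6)
  expect_equal(unname(predict(mm, m)["tI", ]), rep(5, n_ref),
               tolerance = 1e-6)

  # too few reference samples for the parameter count
  expect_error(fit_marker_model(m[, 1:4], meta[1:4, ]), "reference")
})

test_that("log2-ratio normalization subtracts the predicted profile", {
  st <- small_study(seed = 6)
  mm <- st$marker_model
  pred <- predict(mm, st$gene)
  # observed = predicted => ratio 0 everywhere
  ident <- expr_matrix(pred, "log2_intensity")
  r0 <- normalize_log2ratio(ident, mm)
  expect_lt(max(abs(r0)), 1e-8)
  # observed = baseline + 1 (a log2 doubling) => +1 everywhere
  base1 <- rowMeans(pred)
  r1 <- normalize_log2ratio(expr_matrix(sweep(pred * 0, 1, base1 + 1, `+`),
                                        "log2_intensity"),
                            baseline = base1)
  expect_true(all(abs(r1 - 1) < 1e-8))
  # OLS residual property: reference samples' mean ratio per gene ~ 0
  ref <- mm$reference_sample_ids
  ratios <- st$ratios
  expect_lt(max(abs(rowMeans(ratios[, ref]))), 1e-8)
  # baseline mode
  base <- rowMeans(st$gene[, ref])
  rb <- normalize_log2ratio(st$gene, baseline = base)
  expect_equal(as.numeric(rb[, ref[1]]),
               as.numeric(st$gene[, ref[1]] - base), tolerance = 1e-10)
  expect_identical(attr(rb, "scale"), "log2_ratio")
})

test_that("marker normalization removes most of the batch variance", {
  reductions <- vapply(1:5, function(s) {
    st <- small_study(seed = s, batch_effect_sd = 0.8)
    ref <- st$marker_model$reference_sample_ids
    base <- rowMeans(st$gene[, ref])
    raw_ratio <- st$gene - base            # unnormalized ratios
    batch <- st$meta$batch[match(colnames(st$gene), st$meta$sample_id)]
    batch_var <- function(vals) {
      centered <- colMeans(vals)
      mean(tapply(centered, batch, mean)^2)
    }
    1 - batch_var(st$ratios) / batch_var(raw_ratio)
  }, numeric(1))
  expect_true(all(reductions >= 0.5))
})

test_that("study loading enforces its contracts", {
  dir <- withr::local_tempdir()
  st <- small_study(seed = 2)
  paths <- write_study_bundle(st$cohort, dir)

  # GMT member absent from the matrix -> dropped with warning
  writeLines(c("SETA\tdesc\tg00001\tgX"), file.path(dir, "bad.gmt"))
  expect_warning(
    out <- load_study(paths["expression"], paths["meta"],
                      file.path(dir, "bad.gmt")),
    "absent")
  expect_identical(out$sets$SETA, "g00001")

  # metadata missing a matrix column -> error naming the sample
  meta <- st$meta[-1, ]
  badmeta <- file.path(dir, "badmeta.tsv")
  write.table(meta, badmeta, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_study(paths["expression"], badmeta), st$meta$sample_id[1])
})
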