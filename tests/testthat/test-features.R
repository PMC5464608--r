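ratio_matrix <- function(vals, samples, genes) {
  expr_matrix(matrix(vals, length(genes), length(samples),
                     dimnames = list(genes, samples)), "log2_ratio")
}

toy_meta <- function(samples, classes, batch = 1) {
  data.frame(sample_id = samples, class = classes, batch = batch,
             stringsAsFactors = FALSE)
}

test_that("differential statistics match a hand-computed Welch test", {
  a <- c(0.1, -0.3, 0.25); b <- c(1.0, 1.4, 0.8)
  vals <- rbind(g1 = c(a, b), g2 = rep(0.5, 6), g3 = c(-1, -1, -1, 0, 0, 0))
  colnames(vals) <- paste0("s", 1:6)
  m <- expr_matrix(vals, "log2_ratio")
  meta <- toy_meta(paste0("s", 1:6),
                   rep(c("carrier", "non-carrier"), each = 3))
  d <- differential_stats(m, meta)
  or <- t.test(a, b)
  expect_equal(d$genes$t[1], unname(or$statistic), tolerance = 1e-10)
  expect_equal(d$genes$p[1], or$p.value, tolerance = 1e-10)
  expect_equal(d$genes$mean_diff[1], mean(a) - mean(b), tolerance = 1e-12)
  # identical class distributions: zero fold change, flagged zero variance
  expect_equal(d$genes$mean_diff[2], 0)
  expect_true(d$genes$flagged[2])
  expect_equal(d$genes$p[2], 1)
  # disease mean -1, control mean 0
  expect_equal(d$genes$mean_diff[3], -1)
})

test_that("maxmean scoring follows the direct formula", {
  # member scores (+2, -1): positive part mean 1 beats negative part 0.5
  expect_equal(icapr:::maxmean_stat(c(2, -1)), 1)
  expect_equal(icapr:::maxmean_stat(c(-2, 1)), -1)
  expect_equal(icapr:::maxmean_stat(c(0, 0, 0)), 0)

  # raw (unstandardized) scores flow through gsa_scores
  m <- ratio_matrix(c(2, 2, 2, 2, -1, -1, -1, -1,
                      0, 0, 0, 0, 0, 0, 0, 0), paste0("s", 1:4),
                    c("gUP", "gDN", "gA", "gB"))
  m["gUP", ] <- c(2, 2, 0, 0); m["gDN", ] <- c(-2, -2, 0, 0)
  m["gA", ] <- rnorm(4, sd = 0.01); m["gB", ] <- rnorm(4, sd = 0.01)
  meta <- toy_meta(paste0("s", 1:4),
                   rep(c("carrier", "non-carrier"), each = 2))
  d <- differential_stats(m, meta)
  g <- gsa_scores(d, list(S1 = c("gUP", "gDN")), m, meta,
                  restandardize = FALSE)
  expected <- icapr:::maxmean_stat(d$genes$t[1:2])
  expect_equal(g$sets$score[1], expected)
  expect_equal(g$sets$score_raw[1], expected)

  # all-zero gene scores: every set scores 0, nothing selected
  m0 <- ratio_matrix(rep(0, 12), paste0("s", 1:4), c("g1", "g2", "g3"))
  d0 <- differential_stats(m0, meta)
  g0 <- gsa_scores(d0, list(S1 = c("g1", "g2"), S2 = "g3"), m0, meta,
                   restandardize = FALSE)
  expect_true(all(g0$sets$score == 0))
  expect_length(select_sets(g0, "two_sided"), 0)
})

test_that("restandardized scores recover planted down-regulated sets", {
  hit <- vapply(1:5, function(s) {
    st <- small_study(seed = s, n_per_class = 20)
    d <- differential_stats(st$ratios, st$meta)
    g <- gsa_scores(d, st$sets, st$ratios, st$meta, n_perm = 100, seed = s)
    sel <- select_sets(g, "down_only")
    mean(st$truth$responsive_set_ids %in% sel)
  }, numeric(1))
  expect_gte(mean(hit), 0.8)
})

test_that("restandardization commutes with a global sign flip", {
  st <- small_study(seed = 8)
  d <- differential_stats(st$ratios, st$meta)
  g1 <- gsa_scores(d, st$sets, st$ratios, st$meta, n_perm = 50, seed = 2)
  # flip the classes: every gene score negates
  meta_flip <- st$meta
  meta_flip$class <- ifelse(meta_flip$class == "carrier", "non-carrier",
                            "carrier")
  d2 <- differential_stats(st$ratios, meta_flip)
  g2 <- gsa_scores(d2, st$sets, st$ratios, meta_flip, n_perm = 50, seed = 2)
  expect_equal(g2$sets$score_raw, -g1$sets$score_raw, tolerance = 1e-8)
})

test_that("aggregate set features are member means and commute with reorder", {
  m <- ratio_matrix(c(0.4, -0.2, 1.0, 0.4, -0.2, 1.0), paste0("s", 1:2),
                    c("g1", "g2", "g3"))
  f <- aggregate_set_features(m, list(A = c("g1", "g2"), B = "g3"))
  expect_equal(unname(f["s1", "A"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(f[, "B"]), unname(m["g3", ]))  # singleton identity
  f2 <- aggregate_set_features(m[, c("s2", "s1")],
                               list(A = c("g1", "g2"), B = "g3"))
  expect_equal(f2[c("s1", "s2"), ], f[c("s1", "s2"), ])
})

test_that("gene filtering keeps union members with matching evidence", {
  # a modest effect so that set-level selection succeeds while some member
  # genes lack individual evidence (the 263 -> 134 style reduction)
  st <- small_study(seed = 12, effect_size = -0.3, n_per_class = 8)
  d <- differential_stats(st$ratios, st$meta)
  g <- gsa_scores(d, st$sets, st$ratios, st$meta, n_perm = 100, seed = 1)
  sel <- select_sets(g, "down_only")
  genes <- filter_genes_in_sets(g, sel, d, alpha = 0.05)
  union_genes <- unique(unlist(g$members[sel], use.names = FALSE))
  expect_true(all(genes %in% union_genes))
  expect_lt(length(genes), length(union_genes))  # a strict subset
  gtab <- d$genes[match(genes, d$genes$gene), ]
  expect_true(all(gtab$p < 0.05))
  # a gene with p = 0.5 can never pass alpha = 0.05
  expect_false(any(gtab$p > 0.05))
})

test_that("the joint score is the geometric mean of percentile ranks", {
  d <- structure(list(genes = data.frame(
    gene = c("g1", "g2", "g3"),
    mean_diff = c(-1.0, -0.5, 0.1),
    t = c(-5, -2, 0.3), df = c(4, 4, 4),
    p = c(0.001, 0.04, 0.8), flagged = FALSE,
    stringsAsFactors = FALSE)), class = "diff_result")
  js <- ad_joint_score(d)
  # best gene in both active metrics, neutral set evidence
  expect_equal(js$score[js$gene == "g1"], (1 * 1 * 0.5)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(js$gene[1], "g1")
  # hand-assigned ranks (1, 0.5, 0.5) give ~0.630
  expect_equal((1 * 0.5 * 0.5)^(1 / 3), 0.62996, tolerance = 1e-4)
  # improving one metric with others fixed never lowers the score
  d2 <- d; d2$genes$p[2] <- 0.0001
  js2 <- ad_joint_score(d2)
  expect_gte(js2$score[js2$gene == "g2"], js$score[js$gene == "g2"])
})

test_that("cluster features recover planted co-expression blocks", {
  set.seed(3)
  n <- 40
  driver1 <- rnorm(n); driver2 <- rnorm(n)
  block1 <- t(sapply(1:8, function(i) driver1 + rnorm(n, sd = 0.2)))
  block2 <- t(sapply(1:8, function(i) driver2 + rnorm(n, sd = 0.2)))
  noise <- matrix(rnorm(30 * n), 30, n)
  vals <- rbind(block1, block2, noise)
  dimnames(vals) <- list(paste0("g", seq_len(nrow(vals))),
                         paste0("s", seq_len(n)))
  m <- expr_matrix(vals, "log2_ratio")
  f <- cluster_features(m, min_size = 5, max_size = 15)
  members <- attr(f, "members")
  expect_gte(length(members), 2)
  b1 <- paste0("g", 1:8); b2 <- paste0("g", 9:16)
  recov1 <- max(vapply(members, function(mm)
    length(intersect(mm, b1)) / 8, numeric(1)))
  recov2 <- max(vapply(members, function(mm)
    length(intersect(mm, b2)) / 8, numeric(1)))
  expect_gte(recov1, 0.9)
  expect_gte(recov2, 0.9)
  # label-blind: permuting sample order leaves memberships unchanged
  perm <- sample(colnames(m))
  f2 <- cluster_features(m[, perm], min_size = 5, max_size = 15)
  expect_identical(lapply(attr(f2, "members"), sort),
                   lapply(members, sort))
  # clusters below the minimum size are excluded
  expect_true(all(lengths(members) >= 5))
})

test_that("Sturges binning removes the bin containing FWER 1.0", {
  # N = 128: 8 bins of width 0.125
  fw <- setNames(c(0.9, 0.85, rep(0, 126)), paste0("f", 1:128))
  kept <- sturges_filter(fw)
  expect_false("f1" %in% kept)
  expect_true("f2" %in% kept)
  # N = 5: 4 bins; [0.75, 1] removed
  fw5 <- setNames(c(0, 0.2, 0.5, 0.9, 1.0), paste0("f", 1:5))
  expect_setequal(sturges_filter(fw5), c("f1", "f2", "f3"))
  # all-zero FWERs retained; empty input allowed
  expect_length(sturges_filter(setNames(rep(0, 10), paste0("f", 1:10))), 10)
  expect_length(sturges_filter(numeric()), 0)
})
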