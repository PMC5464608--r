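#' Per-gene differential expression statistics
#'
#' Welch two-sample t-test per gene on log2 ratios; fold change is the
#' difference of class means in log2 units (disease minus control).
#' Zero-variance genes get t = 0 and p = 1 by convention and are flagged.
#'
#' @param ratios genes x samples matrix on the `log2_ratio` scale.
#' @param meta sample metadata; classes mapped via [is_disease()].
#' @return object of class `diff_result`: data.frame `genes` with columns
#'   `gene`, `mean_diff`, `t`, `df`, `p`, `flagged`.
#' @export
differential_stats <- function(ratios, meta) {
  check_scale(ratios, "log2_ratio")
  check_meta(ratios, meta)
  cls <- stats::setNames(is_disease(meta$class), meta$sample_id)
  disease <- cls[colnames(ratios)]
  if (any(is.na(disease)))
    stop("samples with unknown class: ",
         paste(colnames(ratios)[is.na(disease)], collapse = ", "))
  if (sum(disease) < 2 || sum(!disease) < 2)
    stop("need >= 2 samples per class")
  w <- welch_t_rows(unclass(ratios), disease)
  res <- list(genes = data.frame(gene = rownames(ratios),
                                 mean_diff = w$mean_diff, t = w$t,
                                 df = w$df, p = w$p, flagged = w$flagged,
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
              n_disease = sum(disease), n_control = sum(!disease))
  class(res) <- "diff_result"
  res
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("Differential expression: %d genes, %d disease vs %d control samples\n",
              nrow(x$genes), x$n_disease, x$n_control))
  cat(sprintf("  %d genes at nominal p < 0.05\n", sum(x$genes$p < 0.05)))
  invisible(x)
}

# maxmean statistic of Efron-Tibshirani type for one set of gene scores:
# the mean positive part vs the mean negative part (both over the full set
# size), signed by whichever dominates. Ties go positive.
maxmean_stat <- function(scores) {
  m <- length(scores)
  sp <- sum(pmax(scores, 0)) / m
  sn <- sum(pmax(-scores, 0)) / m
  if (sp >= sn) sp else -sn
}

# Catalog-restandardized maxmean scores for a list of member-index vectors:
# each half-mean (positive and negative parts over the full set size) is
# standardized by the catalog moments of that part over all gene scores,
# scaled for the set size; the score is the larger standardized half,
# signed. Degenerate catalogs (zero spread) give zero scores.
restandardized_scores <- function(z, idx) {
  mp <- mean(pmax(z, 0)); sp <- stats::sd(pmax(z, 0))
  mn <- mean(pmax(-z, 0)); sn <- stats::sd(pmax(-z, 0))
  vapply(idx, function(i) {
    m <- length(i)
    s_pos <- sum(pmax(z[i], 0)) / m
    s_neg <- sum(pmax(-z[i], 0)) / m
    z_pos <- if (sp > 0) (s_pos - mp) / (sp / sqrt(m)) else 0
    z_neg <- if (sn > 0) (s_neg - mn) / (sn / sqrt(m)) else 0
    if (z_pos >= z_neg) z_pos else -z_neg
  }, numeric(1))
}

#' Gene-set maxmean scores with restandardization
#'
#' Scores every gene set with the maxmean statistic over per-gene Welch t
#' scores. With `restandardize = TRUE` (default) the positive- and
#' negative-part means are standardized against the moments of the observed
#' gene-score catalog (scaled for set size) before the dominant half is
#' chosen — so set scores are expressed in units of what a random gene set
#' of that size would show given the whole dataset, and class-label
#' permutations of the same restandardized statistic provide per-set
#' p-values. Selection masks are reported for the two published regimes:
#' down-only (score <= -threshold) and two-sided (|score| >= threshold),
#' with threshold 1 on the restandardized scale.
#'
#' @param diff a [differential_stats()] result on the same data.
#' @param sets named list of member gene ids.
#' @param ratios,meta the data `diff` was computed from (needed for the
#'   permutations).
#' @param n_perm number of label permutations for the per-set p-values
#'   (default 1000; 0 skips them).
#' @param seed permutation seed.
#' @param threshold selection threshold on the (restandardized) score.
#' @param restandardize set `FALSE` to return raw maxmean scores.
#' @return object of class `gsa_result`: data.frame `sets` with `set`,
#'   `size`, `score_raw`, `score`, `p_perm`, `direction`, `selected_down`,
#'   `selected_two_sided`; plus `gene_best_score` (per-gene best |score| over
#'   containing sets, signed).
#' @export
gsa_scores <- function(diff, sets, ratios, meta, n_perm = 1000, seed = 1L,
                       threshold = 1, restandardize = TRUE) {
  stopifnot(inherits(diff, "diff_result"))
  check_scale(ratios, "log2_ratio")
  sets <- resolve_sets(sets, rownames(ratios))
  if (!length(sets)) stop("no gene sets resolvable against the matrix")
  tvec <- stats::setNames(diff$genes$t, diff$genes$gene)
  idx <- lapply(sets, function(g) match(g, names(tvec)))
  raw <- vapply(idx, function(i) maxmean_stat(tvec[i]), numeric(1))

  p_perm <- rep(NA_real_, length(sets))
  if (restandardize) {
    score <- restandardized_scores(tvec, idx)
    if (n_perm > 0) {
      cls <- stats::setNames(is_disease(meta$class), meta$sample_id)
      disease <- cls[colnames(ratios)]
      vals <- unclass(ratios)
      set.seed(child_seed(seed, 31L))
      exceed <- numeric(length(sets))
      for (b in seq_len(n_perm)) {
        pd <- sample(disease)
        pt <- welch_t_rows(vals, pd)$t
        exceed <- exceed +
          (abs(restandardized_scores(pt, idx)) >= abs(score))
      }
      p_perm <- (exceed + 1) / (n_perm + 1)
    }
  } else {
    score <- raw
  }

  tab <- data.frame(set = names(sets), size = lengths(sets),
                    score_raw = unname(raw), score = unname(score),
                    p_perm = unname(p_perm),
                    direction = ifelse(score >= 0, 1, -1),
                    selected_down = score <= -threshold,
                    selected_two_sided = abs(score) >= threshold,
                    row.names = NULL, stringsAsFactors = FALSE)

  # per-gene best score among containing sets (largest |score|, sign kept)
  gene_best <- stats::setNames(rep(NA_real_, length(tvec)), names(tvec))
  for (j in seq_along(sets)) {
    g <- sets[[j]]
    cur <- gene_best[g]
    replace <- is.na(cur) | abs(score[j]) > abs(cur)
    gene_best[g[replace]] <- score[j]
  }

  structure(list(sets = tab, members = sets, gene_best_score = gene_best,
                 threshold = threshold, n_perm = if (restandardize) n_perm else 0L),
            class = "gsa_result")
}

#' @export
print.gsa_result <- function(x, ...) {
  cat(sprintf("Gene-set maxmean scores: %d sets (%s)\n", nrow(x$sets),
              if (x$n_perm > 0)
                sprintf("restandardized, %d permutations", x$n_perm)
              else "raw"))
  cat(sprintf("  selected: %d down-only (score <= -%g), %d two-sided (|score| >= %g)\n",
              sum(x$sets$selected_down), x$threshold,
              sum(x$sets$selected_two_sided), x$threshold))
  invisible(x)
}

#' Select gene sets under a published regime
#'
#' @param gsa a [gsa_scores()] result.
#' @param regime `"down_only"` (score <= -threshold) or `"two_sided"`
#'   (|score| >= threshold).
#' @return character vector of selected set names.
#' @export
select_sets <- function(gsa, regime = c("down_only", "two_sided")) {
  regime <- match.arg(regime)
  mask <- if (regime == "down_only") gsa$sets$selected_down
          else gsa$sets$selected_two_sided
  gsa$sets$set[mask]
}

#' Aggregate gene-set features
#'
#' One feature per selected set: the per-sample mean of member-gene log2
#' ratios ("average differential expression of gene sets as features").
#'
#' @param ratios genes x samples `log2_ratio` matrix.
#' @param sets named list of member gene ids (already selected).
#' @return samples x features numeric matrix.
#' @export
aggregate_set_features <- function(ratios, sets) {
  check_scale(ratios, "log2_ratio")
  sets <- resolve_sets(sets, rownames(ratios))
  if (!length(sets)) stop("no selected sets with resolvable members")
  feats <- vapply(sets, function(g)
    colMeans(ratios[g, , drop = FALSE]), numeric(ncol(ratios)))
  feats <- matrix(feats, ncol = length(sets),
                  dimnames = list(colnames(ratios), names(sets)))
  feats
}

#' Filter member genes of selected sets by individual evidence
#'
#' Takes the union of member genes of the selected sets and keeps those that
#' individually show evidence of differential expression: nominal Welch
#' p < alpha with fold-change sign matching the direction of at least one
#' containing selected set.
#'
#' @param gsa a [gsa_scores()] result.
#' @param selected character vector of selected set names.
#' @param diff the [differential_stats()] result.
#' @param alpha significance level (default 0.05).
#' @return character vector of retained gene ids.
#' @export
filter_genes_in_sets <- function(gsa, selected, diff, alpha = 0.05) {
  members <- gsa$members[selected]
  if (!length(members)) stop("no selected sets")
  dirs <- stats::setNames(gsa$sets$direction, gsa$sets$set)[selected]
  union_genes <- unique(unlist(members, use.names = FALSE))
  gtab <- diff$genes[match(union_genes, diff$genes$gene), ]
  ok_dir <- vapply(seq_along(union_genes), function(i) {
    g <- union_genes[i]
    containing <- selected[vapply(members, function(mm) g %in% mm, logical(1))]
    any(sign(gtab$mean_diff[i]) == dirs[containing])
  }, logical(1))
  keep <- union_genes[gtab$p < alpha & ok_dir]
  if (!length(keep))
    stop("no genes pass the individual-evidence filter; consider a larger alpha")
  keep
}

#' Gene-ratio feature table
#'
#' @param ratios genes x samples `log2_ratio` matrix.
#' @param genes gene ids to use as features.
#' @return samples x genes matrix.
#' @export
gene_features <- function(ratios, genes) {
  check_scale(ratios, "log2_ratio")
  missing <- setdiff(genes, rownames(ratios))
  if (length(missing)) stop("genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  t(ratios[genes, , drop = FALSE])
}

#' Joint probability gene score
#'
#' Ranks genes by a combined score equally weighting three metrics: magnitude
#' of differential expression (|fold change|), significance of differential
#' expression (t-test p-value, smaller better), and gene-set evidence (best
#' |maxmean score| among sets containing the gene). Each metric is converted
#' to an ascending percentile rank in (0, 1] (larger = better) and combined
#' as the geometric mean; genes in no set get the neutral rank 0.5.
#'
#' @param diff a [differential_stats()] result.
#' @param gsa optionally, a [gsa_scores()] result for the set-evidence
#'   component.
#' @return data.frame with `gene`, the three component ranks, `score`,
#'   sorted by decreasing score.
#' @export
ad_joint_score <- function(diff, gsa = NULL) {
  g <- diff$genes
  n <- nrow(g)
  prank <- function(x) rank(x, ties.method = "average") / length(x)
  r_fc <- prank(abs(g$mean_diff))
  r_p <- prank(-g$p)
  if (!is.null(gsa)) {
    best <- abs(gsa$gene_best_score[g$gene])
    r_gsa <- rep(0.5, n)
    has <- !is.na(best)
    r_gsa[has] <- prank(best[has]) * (sum(has) / n) # keep within (0, 1]
  } else r_gsa <- rep(0.5, n)
  score <- (r_fc * r_p * r_gsa)^(1 / 3)
  out <- data.frame(gene = g$gene, rank_fc = r_fc, rank_p = r_p,
                    rank_gsa = r_gsa, score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$score), ]
}

#' Label-blind cluster features
#'
#' Identifies groups of co-regulated genes by average-linkage hierarchical
#' clustering on the 1 - Pearson correlation distance across all samples
#' (class labels are never consulted). The tree is cut at the number of
#' clusters that maximizes how many clusters fall within the configured size
#' bounds; each in-bound cluster becomes one feature, the per-sample mean of
#' member ratios.
#'
#' @param ratios genes x samples `log2_ratio` matrix.
#' @param min_size,max_size cluster size bounds (defaults 5 and 50).
#' @param max_k largest cluster count scanned.
#' @param min_cor coherence floor: a cluster only qualifies when the mean
#'   pairwise correlation of its members reaches this value, which keeps
#'   chance groupings of unrelated genes out of the feature set.
#' @return samples x clusters feature matrix with a `members` attribute
#'   (named list of member genes); zero columns with a warning when no
#'   cluster fits the bounds.
#' @export
cluster_features <- function(ratios, min_size = 5, max_size = 50,
                             max_k = 50, min_cor = 0.4) {
  check_scale(ratios, "log2_ratio")
  v <- unclass(ratios)
  keep <- apply(v, 1, stats::sd) > 0
  v <- v[keep, , drop = FALSE]
  cm <- stats::cor(t(v))
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  qualifying <- function(cl) {
    members <- split(names(cl), cl)
    ok <- vapply(members, function(mm) {
      if (length(mm) < min_size || length(mm) > max_size) return(FALSE)
      sub <- cm[mm, mm]
      mean(sub[lower.tri(sub)]) >= min_cor
    }, logical(1))
    members[ok]
  }
  ks <- 2:min(max_k, nrow(v) - 1)
  n_ok <- vapply(ks, function(k)
    length(qualifying(stats::cutree(hc, k = k))), numeric(1))
  # ties go to the coarsest cut achieving the count (intact clusters)
  k_best <- min(ks[n_ok == max(n_ok)])
  members <- qualifying(stats::cutree(hc, k = k_best))
  if (!length(members)) {
    warning("no cluster within the size bounds; empty feature table")
    out <- matrix(numeric(0), nrow = ncol(ratios), ncol = 0,
                  dimnames = list(colnames(ratios), NULL))
    attr(out, "members") <- list()
    return(out)
  }
  names(members) <- sprintf("CLUST%02d", seq_along(members))
  feats <- vapply(members, function(g)
    colMeans(ratios[g, , drop = FALSE]), numeric(ncol(ratios)))
  feats <- matrix(feats, ncol = length(members),
                  dimnames = list(colnames(ratios), names(members)))
  attr(feats, "members") <- members
  feats
}

#' Sturges FWER binning filter
#'
#' Bins per-feature family-wise error rates into k = ceiling(log2(N)) + 1
#' equal-width bins over [0, 1] and removes features falling in the bin that
#' contains 1.0.
#'
#' @param fwer named numeric vector of FWERs in [0, 1].
#' @return character vector of retained feature ids.
#' @export
sturges_filter <- function(fwer) {
  stopifnot(all(fwer >= 0 & fwer <= 1))
  n <- length(fwer)
  if (n == 0) return(character())
  k <- ceiling(log2(n)) + 1
  cut_low <- (k - 1) / k
  names(fwer)[fwer < cut_low]
}
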