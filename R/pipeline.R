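#' Configuration for one classifier pipeline run
#'
#' The four mode flags span the 16-configuration grid explored for
#' off-signature specificity testing: gene-set selection regime (down-only
#' vs two-sided), feature kind (aggregate gene-set features vs individual
#' genes), shadow-FWER feature selection on or off, and active learning on
#' or off. The remaining knobs control permutation and repetition counts.
#'
#' @param gsa_regime `"down_only"` (score <= -1) or `"two_sided"`
#'   (|score| >= 1).
#' @param feature_kind `"gene_set"` or `"gene"`.
#' @param use_shadow_selection rank features by shadow FWER before building
#'   the ensemble.
#' @param use_active_learning predict the test set through the
#'   minimum-entropy active loop instead of a static ensemble call.
#' @param n_trees forest size for the shadow backend (1000 default; 10000
#'   is the robustness variant).
#' @param n_perm label permutations for gene-set restandardization.
#' @param shadow_reps shadow repetitions.
#' @param gsa_threshold selection threshold on the restandardized score.
#' @param alpha per-gene significance level for the gene-feature filter.
#' @param seed integer seed for all stochastic stages.
#' @return list of class `icap_config`.
#' @export
icap_config <- function(gsa_regime = c("down_only", "two_sided"),
                        feature_kind = c("gene_set", "gene"),
                        use_shadow_selection = TRUE,
                        use_active_learning = FALSE,
                        n_trees = 1000, n_perm = 1000, shadow_reps = 100,
                        gsa_threshold = 1, alpha = 0.05, seed = 1L) {
  cfg <- list(gsa_regime = match.arg(gsa_regime),
              feature_kind = match.arg(feature_kind),
              use_shadow_selection = isTRUE(use_shadow_selection),
              use_active_learning = isTRUE(use_active_learning),
              n_trees = n_trees, n_perm = n_perm, shadow_reps = shadow_reps,
              gsa_threshold = gsa_threshold, alpha = alpha,
              seed = as.integer(seed))
  class(cfg) <- "icap_config"
  cfg
}

#' @export
print.icap_config <- function(x, ...) {
  cat("icap pipeline configuration\n")
  cat(sprintf("  regime %s | features %s | shadow %s | active %s\n",
              x$gsa_regime, x$feature_kind, x$use_shadow_selection,
              x$use_active_learning))
  cat(sprintf("  n_trees %d, n_perm %d, shadow_reps %d, threshold %g, alpha %g, seed %d\n",
              x$n_trees, x$n_perm, x$shadow_reps, x$gsa_threshold, x$alpha,
              x$seed))
  invisible(x)
}

# Select features on training data only; returns the feature constructor
# (applicable to any ratio matrix) plus the ordered feature ids.
select_pipeline_features <- function(ratios, meta, sets, config) {
  diff <- differential_stats(ratios, meta)
  gsa <- gsa_scores(diff, sets, ratios, meta, n_perm = config$n_perm,
                    seed = config$seed, threshold = config$gsa_threshold)
  selected <- select_sets(gsa, config$gsa_regime)
  if (!length(selected)) {
    # degenerate run (e.g. null data): fall back to the single
    # most-extreme set so a classifier always exists
    selected <- if (config$gsa_regime == "down_only")
      gsa$sets$set[which.min(gsa$sets$score)]
    else gsa$sets$set[which.max(abs(gsa$sets$score))]
  }
  if (config$feature_kind == "gene_set") {
    members <- gsa$members[selected]
    build <- function(r) aggregate_set_features(r, members)
    feats <- build(ratios)
  } else {
    genes <- tryCatch(
      filter_genes_in_sets(gsa, selected, diff, alpha = config$alpha),
      error = function(e) {
        union_genes <- unique(unlist(gsa$members[selected],
                                     use.names = FALSE))
        gt <- diff$genes[match(union_genes, diff$genes$gene), ]
        union_genes[order(gt$p)][1]
      })
    build <- function(r) gene_features(r, genes)
    feats <- build(ratios)
  }

  if (config$use_shadow_selection) {
    rk <- compute_fwer(feats, meta$class[match(rownames(feats),
                                               meta$sample_id)],
                       backend = "forest", n_trees = config$n_trees,
                       n_reps = max(20, config$shadow_reps),
                       seed = config$seed)
    ranked <- tryCatch(rank_for_ensemble(rk, cutoff = 1.0),
                       error = function(e) rk$table$feature[1])
  } else {
    # without shadow selection, rank by the selection statistic itself
    ranked <- if (config$feature_kind == "gene_set") {
      sc <- stats::setNames(gsa$sets$score, gsa$sets$set)[colnames(feats)]
      colnames(feats)[order(-abs(sc))]
    } else {
      pv <- stats::setNames(diff$genes$p, diff$genes$gene)[colnames(feats)]
      colnames(feats)[order(pv)]
    }
  }
  list(build = build, features = feats, ranked = ranked,
       selected_sets = selected, diff = diff, gsa = gsa)
}

#' Run one classifier configuration end to end
#'
#' Trains the full selection-to-ensemble chain on the training cohort
#' (log2-ratio matrices; all selection happens on training data only) and
#' predicts the test cohort, statically or through the active-learning loop
#' with the test labels as the sealed oracle.
#'
#' @param train_ratios,train_meta training cohort (`log2_ratio` matrix and
#'   metadata).
#' @param sets gene-set collection.
#' @param test_ratios,test_meta test cohort; `test_meta` supplies the sealed
#'   oracle labels for active learning and the truth for metrics (its class
#'   may be `unknown` for fully blind use).
#' @param config an [icap_config()].
#' @return list of class `icap_run`: `prediction` (per-sample table),
#'   `metrics` ([confusion_metrics()] when truth is known), `n_features`,
#'   `selected_sets`, `config`.
#' @export
run_icap_config <- function(train_ratios, train_meta, sets, test_ratios,
                            test_meta, config = icap_config()) {
  sel <- select_pipeline_features(train_ratios, train_meta, sets, config)
  train_labels <- train_meta$class[match(rownames(sel$features),
                                         train_meta$sample_id)]
  test_feats <- sel$build(test_ratios)

  truth <- stats::setNames(test_meta$class, test_meta$sample_id)
  if (config$use_active_learning) {
    oracle_labels <- ifelse(is_disease(truth) %in% TRUE, "carrier",
                            "non-carrier")
    names(oracle_labels) <- names(truth)
    tr <- active_loop(sel$features, train_labels, test_feats,
                      oracle = oracle_labels, ranked_ids = sel$ranked,
                      seed = config$seed)
    pred_tab <- data.frame(sample_id = tr$transcript$sample_id,
                           probability = tr$transcript$probability,
                           label = tr$transcript$prediction,
                           stringsAsFactors = FALSE)
    votes <- NULL
  } else {
    ens <- icap_ensemble(sel$features, train_labels, sel$ranked,
                         seed = config$seed)
    pr <- predict(ens, test_feats)
    pred_tab <- pr$table[, c("sample_id", "probability", "label")]
    votes <- stats::setNames(pr$table$votes, pr$table$sample_id)
  }

  actual <- truth[pred_tab$sample_id]
  metrics <- NULL
  if (!any(actual == "unknown") && !anyNA(is_disease(actual)) &&
      length(unique(is_disease(actual))) == 2)
    metrics <- confusion_metrics(pred_tab$label, actual)
  structure(list(prediction = pred_tab, metrics = metrics, votes = votes,
                 n_features = length(sel$ranked),
                 selected_sets = sel$selected_sets, config = config),
            class = "icap_run")
}

#' @export
print.icap_run <- function(x, ...) {
  cat("icap pipeline run:", x$n_features, "ensemble feature(s)\n")
  print(x$config)
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Run the 16-configuration grid
#'
#' Executes every logical combination of the four mode flags on a training
#' cohort, predicting both a true-signature test cohort and an off-signature
#' cohort. For each configuration the fraction of off-signature samples
#' correctly called non-carrier is tallied, alongside the test-set metrics.
#'
#' @inheritParams run_icap_config
#' @param offsig_ratios,offsig_meta off-signature cohort.
#' @param base_config an [icap_config()] supplying the non-flag knobs.
#' @return data.frame with one row per configuration: the four flags,
#'   `n_features`, `test_accuracy`, `test_sensitivity`, `test_specificity`,
#'   `offsig_noncarrier_rate`.
#' @export
run_icap_grid <- function(train_ratios, train_meta, sets, test_ratios,
                          test_meta, offsig_ratios, offsig_meta,
                          base_config = icap_config()) {
  flags <- expand.grid(gsa_regime = c("down_only", "two_sided"),
                       feature_kind = c("gene_set", "gene"),
                       use_shadow_selection = c(TRUE, FALSE),
                       use_active_learning = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(flags)), function(i) {
    cfg <- base_config
    cfg$gsa_regime <- flags$gsa_regime[i]
    cfg$feature_kind <- flags$feature_kind[i]
    cfg$use_shadow_selection <- flags$use_shadow_selection[i]
    cfg$use_active_learning <- flags$use_active_learning[i]
    run <- run_icap_config(train_ratios, train_meta, sets, test_ratios,
                           test_meta, cfg)
    off <- run_icap_config(train_ratios, train_meta, sets, offsig_ratios,
                           offsig_meta, cfg)
    off_rate <- mean(!(is_disease(off$prediction$label) %in% TRUE))
    data.frame(flags[i, , drop = FALSE], n_features = run$n_features,
               test_accuracy = if (!is.null(run$metrics))
                 run$metrics$accuracy else NA_real_,
               test_sensitivity = if (!is.null(run$metrics))
                 run$metrics$sensitivity else NA_real_,
               test_specificity = if (!is.null(run$metrics))
                 run$metrics$specificity else NA_real_,
               offsig_noncarrier_rate = off_rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
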