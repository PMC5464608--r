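#' Configuration for a synthetic indicator-cell study
#'
#' Describes a simulated serum-exposure study: a gene universe measured at the
#' exon level, a gene-set collection with a subset of "responsive" sets whose
#' member genes shift in disease samples, per-batch technical effects whose
#' magnitude is linearly encoded in four reserved marker genes, Gaussian
#' per-gene noise, and optional corrupted (outlier) arrays.
#'
#' Defaults mirror the study design the simulator emulates: 25 samples per
#' class assayed in 7 batches, a ~20,000-gene universe with several exons per
#' gene, and a down-regulated disease signature of moderate size
#' (`effect_size = -0.5` log2 units against `noise_sd = 0.25`).
#'
#' @param n_genes number of genes, including the 4 reserved marker genes.
#' @param exons_per_gene integer range (length 2) of exons per gene.
#' @param n_gene_sets number of gene sets in the collection.
#' @param set_size_range integer range (length 2) of set sizes.
#' @param n_responsive_sets how many sets carry the disease signature.
#' @param effect_size log2-unit shift applied to responsive-set member genes in
#'   disease samples; negative means down-regulated.
#' @param noise_sd per-gene Gaussian noise SD (log2 units).
#' @param n_batches number of assay batches; samples are assigned so each batch
#'   holds an equal number of disease and control samples.
#' @param batch_effect_sd SD of the per-batch latent technical shift.
#' @param marker_coupling length-4 numeric, coefficients tying each marker
#'   gene's reading to the batch shift.
#' @param n_per_class samples per class.
#' @param n_outlier_arrays number of arrays corrupted with tripled noise.
#' @param prop_up_sets fraction of responsive sets perturbed upward rather than
#'   down (0 gives the all-down signature used by the down-only selection
#'   regime).
#' @param disease_subclass_split in AD mode, fraction of disease samples
#'   labelled preclinical (the rest early-symptomatic); both share one
#'   signature and one class label.
#' @param mode `"als"` (carrier vs non-carrier) or `"ad"` (AD vs normal, with
#'   an APOE4 allele-count covariate).
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical cohorts.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 20000,
                         exons_per_gene = c(2L, 5L),
                         n_gene_sets = 200,
                         set_size_range = c(10L, 50L),
                         n_responsive_sets = 10,
                         effect_size = -0.5,
                         noise_sd = 0.25,
                         n_batches = 7,
                         batch_effect_sd = 0.5,
                         marker_coupling = c(1.0, 0.8, -0.6, 0.4),
                         n_per_class = 25,
                         n_outlier_arrays = 0,
                         prop_up_sets = 0,
                         disease_subclass_split = 0.5,
                         mode = c("als", "ad"),
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(exons_per_gene) == 2, exons_per_gene[1] >= 1,
            exons_per_gene[2] >= exons_per_gene[1],
            length(set_size_range) == 2,
            set_size_range[2] >= set_size_range[1],
            length(marker_coupling) == 4,
            n_per_class >= 2, n_batches >= 1, noise_sd > 0,
            prop_up_sets >= 0, prop_up_sets <= 1)
  if (n_responsive_sets > n_gene_sets)
    stop("n_responsive_sets must not exceed n_gene_sets")
  if (n_gene_sets * set_size_range[2] > n_genes - 4)
    stop("gene-set collection cannot exceed the non-marker gene universe")
  if (n_batches > 2 * n_per_class)
    stop("more batches than samples")
  if (n_outlier_arrays > 2 * n_per_class)
    stop("more outlier arrays than samples")
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              n_responsive_sets = as.integer(n_responsive_sets),
              effect_size = effect_size, noise_sd = noise_sd,
              n_batches = as.integer(n_batches),
              batch_effect_sd = batch_effect_sd,
              marker_coupling = marker_coupling,
              n_per_class = as.integer(n_per_class),
              n_outlier_arrays = as.integer(n_outlier_arrays),
              prop_up_sets = prop_up_sets,
              disease_subclass_split = disease_subclass_split,
              mode = mode, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic indicator-cell study configuration (", x$mode, " mode)\n",
      sep = "")
  cat(sprintf("  %d genes (%d-%d exons each), %d gene sets (%d responsive)\n",
              x$n_genes, x$exons_per_gene[1], x$exons_per_gene[2],
              x$n_gene_sets, x$n_responsive_sets))
  cat(sprintf("  effect %.3g log2, noise SD %.3g, %d batches (SD %.3g)\n",
              x$effect_size, x$noise_sd, x$n_batches, x$batch_effect_sd))
  cat(sprintf("  %d samples/class, %d outlier arrays, seed %d\n",
              x$n_per_class, x$n_outlier_arrays, x$seed))
  invisible(x)
}

MARKER_GENES <- c("Olig2", "Mnx1", "Isl1", "Lhx3")

# Draw the study-level parameters (gene baselines, batch susceptibilities,
# exon structure, gene sets, responsive sets). Depends only on config$seed.
draw_study_params <- function(config) {
  set.seed(child_seed(config$seed, 1L))
  n_genes <- config$n_genes
  gene_ids <- c(sprintf("g%05d", seq_len(n_genes - 4L)), MARKER_GENES)
  mu <- stats::runif(n_genes, 6, 10)
  names(mu) <- gene_ids
  susceptibility <- stats::rnorm(n_genes, mean = 1, sd = 0.25)
  names(susceptibility) <- gene_ids
  n_exons <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                    n_genes, replace = TRUE)
  names(n_exons) <- gene_ids

  # Disjoint gene sets sampled from the non-marker universe.
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_gene_sets, replace = TRUE)
  pool <- sample(setdiff(gene_ids, MARKER_GENES), sum(sizes))
  sets <- split(pool, rep(seq_along(sizes), sizes))
  names(sets) <- sprintf("SET%03d", seq_along(sets))
  attr(sets, "source") <- "synthetic"

  responsive <- sort(sample(names(sets), config$n_responsive_sets))
  base_dir <- if (config$effect_size > 0) 1 else -1
  direction <- stats::setNames(rep(base_dir, length(responsive)), responsive)
  n_up <- round(config$prop_up_sets * length(responsive))
  if (n_up > 0) direction[sample(responsive, n_up)] <- -base_dir

  list(gene_ids = gene_ids, mu = mu, susceptibility = susceptibility,
       n_exons = n_exons, sets = sets, responsive = responsive,
       direction = direction, config = config)
}

# Simulate one block of samples on the exon level. `perturbed` is a named
# direction vector over set names; member genes of those sets shift by
# effect_size * direction in samples flagged diseased.
simulate_samples <- function(params, sample_ids, diseased, batch_ids,
                             perturbed, outlier_ids, seed) {
  set.seed(seed)
  config <- params$config
  n_genes <- config$n_genes
  n_samp <- length(sample_ids)
  batches <- sort(unique(batch_ids))
  beta <- stats::setNames(stats::rnorm(length(batches), 0,
                                       config$batch_effect_sd), batches)

  gene_vals <- matrix(params$mu, nrow = n_genes, ncol = n_samp,
                      dimnames = list(params$gene_ids, sample_ids))
  # batch shift, linearly encoded in the markers
  shift <- beta[as.character(batch_ids)]
  gene_vals <- gene_vals + outer(params$susceptibility, shift)
  marker_rows <- match(MARKER_GENES, params$gene_ids)
  gene_vals[marker_rows, ] <- params$mu[marker_rows] +
    outer(config$marker_coupling, shift)

  # planted disease signature
  if (length(perturbed)) {
    for (set_name in names(perturbed)) {
      members <- params$sets[[set_name]]
      gene_vals[members, diseased] <- gene_vals[members, diseased] +
        abs(config$effect_size) * perturbed[[set_name]]
    }
  }

  # per-gene noise; outlier arrays get tripled SD, markers a reduced SD so
  # they stay informative about the batch shift
  sd_by_sample <- ifelse(sample_ids %in% outlier_ids,
                         3 * config$noise_sd, config$noise_sd)
  noise <- matrix(stats::rnorm(n_genes * n_samp), n_genes, n_samp)
  noise <- sweep(noise, 2, sd_by_sample, `*`)
  noise[marker_rows, ] <- noise[marker_rows, ] / 5
  gene_vals <- gene_vals + noise

  # exon level: gene value + iid Gaussian exon offset (SD = noise_sd / 2)
  n_exons <- params$n_exons
  total_exons <- sum(n_exons)
  gene_of_exon <- rep(params$gene_ids, n_exons)
  exon_ids <- paste0(gene_of_exon, "_e",
                     unlist(lapply(n_exons, seq_len), use.names = FALSE))
  exon_sd <- ifelse(sample_ids %in% outlier_ids,
                    3 * config$noise_sd / 2, config$noise_sd / 2)
  exon_noise <- matrix(stats::rnorm(total_exons * n_samp), total_exons, n_samp)
  exon_noise <- sweep(exon_noise, 2, exon_sd, `*`)
  exon_vals <- gene_vals[rep(seq_len(n_genes), n_exons), ] + exon_noise
  dimnames(exon_vals) <- list(exon_ids, sample_ids)

  exon_matrix(exon_vals, stats::setNames(gene_of_exon, exon_ids))
}

# Balanced batch assignment: within each class, samples are dealt round-robin
# across batches in random order, so every batch assays (near-)equal numbers
# of disease and control samples.
balanced_batches <- function(n_per_class, n_batches, classes) {
  assign_one <- function(n) {
    b <- rep_len(seq_len(n_batches), n)
    sample(b)
  }
  unlist(lapply(unique(classes), function(cl) assign_one(sum(classes == cl))),
         use.names = FALSE)
}

#' Generate a synthetic training cohort
#'
#' Simulates an exon-level expression matrix for a two-class serum-exposure
#' study together with sample metadata, the gene-set collection, and a ground
#' truth object recording which sets and genes carry the planted signature.
#'
#' @param config a [synth_config()].
#' @return a list with elements `exons` (an `exon_matrix`), `meta` (a
#'   data.frame with `sample_id`, `class`, `batch`, `apoe4_count`), `sets`
#'   (named list of member gene ids) and `truth` (class `ground_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  params <- draw_study_params(config)
  n <- config$n_per_class
  classes <- if (config$mode == "als") {
    rep(c("carrier", "non-carrier"), each = n)
  } else rep(c("AD", "normal"), each = n)
  sample_ids <- sprintf("S%03d", seq_len(2 * n))

  set.seed(child_seed(config$seed, 2L))
  batch_ids <- balanced_batches(n, config$n_batches, classes)
  outlier_ids <- if (config$n_outlier_arrays > 0)
    sample(sample_ids, config$n_outlier_arrays) else character()

  exons <- simulate_samples(params, sample_ids, classes %in% DISEASE_LABELS,
                            batch_ids, params$direction, outlier_ids,
                            child_seed(config$seed, 3L))

  apoe4 <- rep(NA_integer_, 2 * n)
  subclass <- rep(NA_character_, 2 * n)
  if (config$mode == "ad") {
    set.seed(child_seed(config$seed, 4L))
    dis <- classes == "AD"
    apoe4[dis] <- sample(0:2, sum(dis), TRUE, prob = c(0.35, 0.45, 0.20))
    apoe4[!dis] <- sample(0:2, sum(!dis), TRUE, prob = c(0.75, 0.22, 0.03))
    n_pre <- round(config$disease_subclass_split * sum(dis))
    subclass[dis] <- rep(c("preclinical", "early-symptomatic"),
                         c(n_pre, sum(dis) - n_pre))
  }
  meta <- data.frame(sample_id = sample_ids, class = classes,
                     batch = batch_ids, apoe4_count = apoe4,
                     subclass = subclass, stringsAsFactors = FALSE)

  truth <- list(responsive_set_ids = params$responsive,
                responsive_gene_ids =
                  sort(unlist(params$sets[params$responsive],
                              use.names = FALSE)),
                direction_by_set = params$direction,
                outlier_sample_ids = sort(outlier_ids))
  class(truth) <- "ground_truth"
  attr(truth, "params") <- params

  list(exons = exons, meta = meta, sets = params$sets, truth = truth)
}

#' Generate an off-signature disease cohort
#'
#' Simulates a second disease cohort (a Huntington's-style analog) whose
#' perturbation lies in gene sets disjoint from the planted signature in
#' `truth`, so a classifier trained on the original signature should call
#' these samples non-carriers.
#'
#' @param config the [synth_config()] used for the original cohort.
#' @param truth the `ground_truth` returned by [generate_cohort()].
#' @param n_samples number of off-signature samples (default 6).
#' @param seed seed for the new samples (defaults to `config$seed + 1`).
#' @return list with `exons` and `meta`; the perturbed set names are attached
#'   as attribute `perturbed_sets`.
#' @export
generate_offsignature_cohort <- function(config, truth, n_samples = 6,
                                         seed = config$seed + 1L) {
  params <- attr(truth, "params")
  if (is.null(params)) stop("truth must come from generate_cohort()")
  avail <- setdiff(names(params$sets), truth$responsive_set_ids)
  if (length(avail) < config$n_responsive_sets)
    stop("no disjoint gene sets available for an off-signature cohort")
  set.seed(child_seed(seed, 10L))
  chosen <- sort(sample(avail, config$n_responsive_sets))
  direction <- stats::setNames(rep(-1, length(chosen)), chosen)

  sample_ids <- sprintf("H%03d", seq_len(n_samples))
  batch_ids <- rep_len(config$n_batches + seq_len(max(1, n_samples %/% 6)),
                       n_samples)
  exons <- simulate_samples(params, sample_ids, rep(TRUE, n_samples),
                            batch_ids, direction, character(),
                            child_seed(seed, 11L))
  meta <- data.frame(sample_id = sample_ids, class = "off-signature",
                     batch = batch_ids, apoe4_count = NA_integer_,
                     subclass = NA_character_, stringsAsFactors = FALSE)
  out <- list(exons = exons, meta = meta)
  attr(out, "perturbed_sets") <- chosen
  out
}

#' Generate an independent validation cohort sharing the planted signature
#'
#' Emulates a blinded hold-out set: new samples with the same responsive sets
#' as the training cohort but freshly drawn batches (so train and test differ
#' by a technical batch shift).
#'
#' @inheritParams generate_offsignature_cohort
#' @param n_per_class samples per class in the validation set (default 6).
#' @return list with `exons` and `meta`.
#' @export
generate_validation_cohort <- function(config, truth, n_per_class = 6,
                                       seed = config$seed + 2L) {
  params <- attr(truth, "params")
  if (is.null(params)) stop("truth must come from generate_cohort()")
  classes <- if (config$mode == "als") {
    rep(c("carrier", "non-carrier"), each = n_per_class)
  } else rep(c("AD", "normal"), each = n_per_class)
  sample_ids <- sprintf("V%03d", seq_len(2 * n_per_class))
  set.seed(child_seed(seed, 20L))
  n_new_batches <- max(1L, as.integer(ceiling(2 * n_per_class / 8)))
  batch_ids <- 100L + balanced_batches(n_per_class, n_new_batches, classes)
  exons <- simulate_samples(params, sample_ids, classes %in% DISEASE_LABELS,
                            batch_ids, params$direction, character(),
                            child_seed(seed, 21L))
  meta <- data.frame(sample_id = sample_ids, class = classes,
                     batch = batch_ids, apoe4_count = NA_integer_,
                     subclass = NA_character_, stringsAsFactors = FALSE)
  list(exons = exons, meta = meta)
}

#' Write a study bundle to disk
#'
#' Writes the standard plain-text bundle: an expression TSV (first column exon
#' id, second column gene id, remaining columns samples), a GMT gene-set file,
#' a metadata TSV and a ground-truth JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_study_bundle <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             sets = file.path(dir, "sets.gmt"),
             meta = file.path(dir, "meta.tsv"),
             truth = file.path(dir, "truth.json"))
  ex <- cohort$exons
  df <- data.frame(exon_id = rownames(ex$values),
                   gene_id = unname(ex$exon_to_gene[rownames(ex$values)]),
                   ex$values, check.names = FALSE)
  utils::write.table(df, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt <- vapply(names(cohort$sets), function(nm) {
    paste(c(nm, "synthetic", cohort$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, paths["sets"])
  utils::write.table(cohort$meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(responsive_set_ids = truth$responsive_set_ids,
         responsive_gene_ids = truth$responsive_gene_ids,
         direction_by_set = as.list(truth$direction_by_set),
         outlier_sample_ids = truth$outlier_sample_ids),
    paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
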