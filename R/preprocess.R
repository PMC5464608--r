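#' Exon-level expression container
#'
#' @param values numeric matrix, exons x samples (normalized log2
#'   intensities), with unique exon ids as row names.
#' @param exon_to_gene named character vector mapping every exon id to exactly
#'   one gene id.
#' @return object of class `exon_matrix`.
#' @export
exon_matrix <- function(values, exon_to_gene) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyDuplicated(rownames(values))) stop("duplicate exon ids")
  if (!all(rownames(values) %in% names(exon_to_gene)))
    stop("every exon must map to a gene")
  structure(list(values = values,
                 exon_to_gene = exon_to_gene[rownames(values)]),
            class = "exon_matrix")
}

#' @export
print.exon_matrix <- function(x, ...) {
  cat(sprintf("exon_matrix: %d exons / %d genes x %d samples\n",
              nrow(x$values), length(unique(x$exon_to_gene)),
              ncol(x$values)))
  invisible(x)
}

#' Load a study bundle from disk
#'
#' Reads an expression TSV (header row of sample ids; first column exon or
#' gene id; optional second column `gene_id` marking an exon-level file), a
#' GMT gene-set file and a metadata TSV. Gene-set members absent from the
#' matrix are dropped with a warning; a metadata/matrix sample mismatch is a
#' hard failure naming the sample.
#'
#' @param expression path to the expression TSV.
#' @param meta path to the metadata TSV (`sample_id`, `class`, `batch`,
#'   optional `apoe4_count`).
#' @param sets path to the GMT file, or `NULL`.
#' @return list with `expr` (an `exon_matrix` or gene-level matrix on the
#'   `log2_intensity` scale), `meta`, and `sets`.
#' @export
load_study <- function(expression, meta, sets = NULL) {
  tab <- utils::read.delim(expression, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_df <- utils::read.delim(meta, stringsAsFactors = FALSE)
  if (anyDuplicated(meta_df$sample_id))
    stop("duplicate sample ids in metadata")

  exon_level <- identical(colnames(tab)[2], "gene_id")
  id_col <- tab[[1]]
  if (anyDuplicated(id_col)) stop("duplicate row ids in expression file")
  first_sample <- if (exon_level) 3L else 2L
  values <- as.matrix(tab[, first_sample:ncol(tab), drop = FALSE])
  rownames(values) <- id_col
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids in matrix")
  missing <- setdiff(colnames(values), meta_df$sample_id)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))

  expr <- if (exon_level) {
    exon_matrix(values, stats::setNames(tab$gene_id, id_col))
  } else {
    expr_matrix(values, "log2_intensity")
  }

  collection <- NULL
  if (!is.null(sets)) {
    collection <- read_gmt(sets)
    genes <- if (exon_level) unique(expr$exon_to_gene) else rownames(values)
    collection <- resolve_sets(collection, genes)
  }
  list(expr = expr, meta = meta_df, sets = collection)
}

#' Read a GMT gene-set file
#'
#' Each line is `set name<TAB>description<TAB>member...`.
#'
#' @param path file path.
#' @return named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

# Drop set members absent from the measured gene universe (warning), and
# drop sets left empty.
resolve_sets <- function(sets, genes) {
  resolved <- lapply(sets, intersect, genes)
  n_drop <- sum(lengths(sets)) - sum(lengths(resolved))
  if (n_drop > 0)
    warning(sprintf("%d gene-set member(s) absent from the matrix; dropped",
                    n_drop))
  resolved[lengths(resolved) > 0]
}

#' Summarize exon-level expression to gene level
#'
#' Gene expression is the arithmetic mean of all exons in the gene, per
#' sample. Gene-level input (a matrix already carrying an expression scale)
#' passes through unchanged.
#'
#' @param m an `exon_matrix`, or a gene-level expression matrix.
#' @return genes x samples matrix on the `log2_intensity` scale.
#' @export
summarize_exons <- function(m) {
  if (!inherits(m, "exon_matrix")) {
    check_scale(m, "log2_intensity")
    return(m)
  }
  gene <- factor(m$exon_to_gene, levels = unique(m$exon_to_gene))
  sums <- rowsum(m$values, gene, reorder = FALSE)
  counts <- as.vector(table(gene)[rownames(sums)])
  expr_matrix(sums / counts, "log2_intensity")
}

# Two-sided Grubbs critical value at level alpha for n observations.
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Flag low-quality arrays by correlation screening
#'
#' Within each batch, every sample is scored by its mean Pearson correlation
#' against the other same-batch samples; the scores are screened with an
#' iterative two-sided Grubbs test (remove the most extreme score while
#' significant), capped at 20% of the batch. Batches with fewer than three
#' samples are skipped with a warning.
#'
#' @param m gene-level expression matrix (`log2_intensity`).
#' @param meta sample metadata with `sample_id` and `batch`.
#' @param alpha Grubbs significance level (default 0.05).
#' @param per_batch compute correlations within batch (default) or across the
#'   whole cohort.
#' @return object of class `qc_report`: data.frame `scores` (sample, batch,
#'   mean Pearson r) and `removed_sample_ids`.
#' @export
qc_outliers <- function(m, meta, alpha = 0.05, per_batch = TRUE) {
  check_meta(m, meta)
  batch_of <- stats::setNames(meta$batch, meta$sample_id)
  groups <- if (per_batch) split(colnames(m), batch_of[colnames(m)])
            else list(all = colnames(m))
  scores <- data.frame(sample_id = character(), batch = character(),
                       avg_r = numeric(), stringsAsFactors = FALSE)
  removed <- character()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < 3) {
      warning(sprintf("batch %s has fewer than 3 samples; QC skipped", g))
      next
    }
    r <- stats::cor(m[, ids, drop = FALSE])
    avg <- (rowSums(r) - 1) / (length(ids) - 1)
    scores <- rbind(scores, data.frame(sample_id = ids, batch = g,
                                       avg_r = unname(avg),
                                       stringsAsFactors = FALSE))
    cap <- ceiling(0.2 * length(ids))
    keep <- avg
    while (length(keep) >= 3 && (length(ids) - length(keep)) < cap) {
      s <- stats::sd(keep)
      if (!is.finite(s) || s == 0) break
      dev <- abs(keep - mean(keep))
      G <- max(dev) / s
      if (G <= grubbs_critical(length(keep), alpha)) break
      worst <- names(keep)[which.max(dev)]
      removed <- c(removed, worst)
      # rescore remaining samples against each other
      left <- setdiff(names(keep), worst)
      if (length(left) < 3) break
      r2 <- stats::cor(m[, left, drop = FALSE])
      keep <- stats::setNames((rowSums(r2) - 1) / (length(left) - 1), left)
    }
  }
  structure(list(scores = scores, removed_sample_ids = removed,
                 alpha = alpha), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Array QC (Grubbs alpha = %.3g): %d sample(s) removed\n",
              x$alpha, length(x$removed_sample_ids)))
  if (length(x$removed_sample_ids))
    cat(" ", paste(x$removed_sample_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the marker-gene batch-normalization model
#'
#' For every target gene, fits an ordinary least-squares model of its log2
#' expression on the four marker genes (plus intercept) across the reference
#' (non-carrier) samples. The fitted model doubles as a standard non-carrier
#' expression profile reference.
#'
#' @param m gene-level matrix (`log2_intensity`).
#' @param meta sample metadata; reference samples are those whose class maps
#'   to control via [is_disease()].
#' @param marker_genes marker gene ids (default the four motor-neuron markers
#'   Olig2, Mnx1, Isl1, Lhx3).
#' @param reference_samples explicit reference sample ids; defaults to all
#'   control-class samples in `meta` present in `m`.
#' @return object of class `marker_model` with `coefficients`
#'   ((1+k) x genes matrix) and `reference_sample_ids`.
#' @export
fit_marker_model <- function(m, meta, marker_genes = MARKER_GENES,
                             reference_samples = NULL) {
  check_scale(m, "log2_intensity")
  if (!all(marker_genes %in% rownames(m)))
    stop("marker gene(s) absent from matrix: ",
         paste(setdiff(marker_genes, rownames(m)), collapse = ", "))
  if (is.null(reference_samples)) {
    ctrl <- meta$sample_id[is_disease(meta$class) %in% FALSE]
    reference_samples <- intersect(colnames(m), ctrl)
  }
  k <- length(marker_genes)
  if (length(reference_samples) < k + 2)
    stop(sprintf("need at least %d reference samples to fit %d markers",
                 k + 2, k))
  X <- cbind(1, t(m[marker_genes, reference_samples, drop = FALSE]))
  colnames(X)[1] <- "(Intercept)"
  Y <- t(m[, reference_samples, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("collinear marker genes; using minimum-norm least squares")
    coefs <- svd_minnorm_coef(X, Y)
  } else {
    coefs <- qr.coef(qrX, Y)
  }
  structure(list(marker_gene_ids = marker_genes, coefficients = coefs,
                 reference_sample_ids = reference_samples),
            class = "marker_model")
}

svd_minnorm_coef <- function(X, Y) {
  s <- svd(X)
  pos <- s$d > max(s$d) * 1e-10
  dinv <- ifelse(pos, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% Y))
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("Marker-gene linear model: %d markers, %d target genes, %d reference samples\n",
              length(x$marker_gene_ids), ncol(x$coefficients),
              length(x$reference_sample_ids)))
  invisible(x)
}

#' @export
predict.marker_model <- function(object, m, ...) {
  check_scale(m, "log2_intensity")
  X <- cbind(1, t(m[object$marker_gene_ids, , drop = FALSE]))
  pred <- t(X %*% object$coefficients)
  dimnames(pred) <- list(colnames(object$coefficients), colnames(m))
  pred
}

#' Convert log2 intensities to log2 expression ratios
#'
#' Subtracts the predicted log2 expression of each gene — from the
#' marker-gene model (batch-corrected reference prediction) or from a fixed
#' baseline profile such as the mean of no-serum control assays — which is
#' the log2 of the linear-scale quotient observed / predicted. Genes with a
#' non-finite prediction are flagged via attribute `excluded_genes` and
#' dropped.
#'
#' @param m gene-level matrix (`log2_intensity`).
#' @param model a `marker_model`, or `NULL` when using `baseline`.
#' @param baseline named numeric baseline profile (log2), used when `model`
#'   is `NULL`.
#' @return genes x samples matrix on the `log2_ratio` scale.
#' @export
normalize_log2ratio <- function(m, model = NULL, baseline = NULL) {
  check_scale(m, "log2_intensity")
  if (!is.null(model)) {
    pred <- predict(model, m)
    common <- intersect(rownames(m), rownames(pred))
    ratios <- m[common, , drop = FALSE] - pred[common, , drop = FALSE]
  } else if (!is.null(baseline)) {
    common <- intersect(rownames(m), names(baseline))
    ratios <- m[common, , drop = FALSE] - baseline[common]
  } else stop("supply a marker model or a baseline profile")
  bad <- rownames(ratios)[!apply(is.finite(ratios), 1, all)]
  if (length(bad)) {
    warning(sprintf("%d gene(s) with non-finite ratios excluded", length(bad)))
    ratios <- ratios[setdiff(rownames(ratios), bad), , drop = FALSE]
  }
  out <- expr_matrix(ratios, "log2_ratio")
  attr(out, "excluded_genes") <- bad
  out
}
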