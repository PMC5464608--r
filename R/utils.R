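# Internal helpers shared across modules.

DISEASE_LABELS <- c("carrier", "AD", "disease")
CONTROL_LABELS <- c("non-carrier", "normal", "control", "off-signature")

#' Map class labels to a disease indicator
#'
#' Disease ("positive") labels are `carrier`, `AD` and `disease`;
#' control labels are `non-carrier`, `normal`, `control` and
#' `off-signature` (off-signature cohorts carry a perturbation disjoint
#' from the trained signature, so their true call is non-carrier).
#' `unknown` maps to `NA`.
#'
#' @param labels character vector of class labels.
#' @return logical vector, `TRUE` for disease.
#' @export
is_disease <- function(labels) {
  out <- rep(NA, length(labels))
  out[labels %in% DISEASE_LABELS] <- TRUE
  out[labels %in% CONTROL_LABELS] <- FALSE
  out
}

#' Declare an expression matrix and its scale
#'
#' Expression matrices are numeric matrices (genes x samples) carrying a
#' declared scale — `log2_intensity` for normalized array intensities or
#' `log2_ratio` after normalization — which downstream consumers check.
#' Subsetting preserves the declaration.
#'
#' @param values numeric matrix with unique gene ids as row names and
#'   sample ids as column names.
#' @param scale `"log2_intensity"` or `"log2_ratio"`.
#' @return the matrix, classed `icap_expr` with a `scale` attribute.
#' @export
expr_matrix <- function(values, scale = c("log2_intensity", "log2_ratio")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  values <- unclass(values)
  attr(values, "scale") <- scale
  class(values) <- c("icap_expr", class(values))
  values
}

#' @export
`[.icap_expr` <- function(x, ..., drop = TRUE) {
  sc <- attr(x, "scale")
  out <- `[`(unclass(x), ..., drop = drop)
  if (is.matrix(out)) {
    attr(out, "scale") <- sc
    class(out) <- c("icap_expr", class(out))
  }
  out
}

expr_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) stop("matrix has no declared expression scale")
  s
}

check_scale <- function(m, expected) {
  if (!identical(expr_scale(m), expected))
    stop(sprintf("expected a matrix on the %s scale, got %s",
                 expected, expr_scale(m)))
  invisible(TRUE)
}

check_meta <- function(m, meta) {
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing))
    stop("metadata missing samples: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

# Vectorized per-gene Welch two-sample t over a genes x samples matrix.
# Returns list(mean_diff, t, df, p, flagged); zero-variance genes get t = 0,
# p = 1 by convention and are flagged.
welch_t_rows <- function(values, disease) {
  stopifnot(is.logical(disease), length(disease) == ncol(values))
  x <- values[, disease, drop = FALSE]
  y <- values[, !disease, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) stop("need >= 2 samples per class")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  flagged <- se2 == 0
  tstat <- ifelse(flagged, 0, (mx - my) / sqrt(se2))
  df <- ifelse(flagged, NA_real_,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), df))
  list(mean_diff = mx - my, t = tstat, df = df, p = p, flagged = flagged)
}

# md5 of a character scalar (via a temp file; base R has no string digest).
md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(x, f, eos = NULL)
  unname(tools::md5sum(f))
}

# Derive a stream-specific child seed from a base seed, kept < 2^31
# (double arithmetic avoids integer overflow for nested derivations).
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream)) %% 2147483647)
}
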