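# Shared fixtures, built in code.

small_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 600, exons_per_gene = c(2L, 4L),
                   n_gene_sets = 30, set_size_range = c(8L, 14L),
                   n_responsive_sets = 6, effect_size = -0.5,
                   noise_sd = 0.25, n_batches = 4, n_per_class = 12,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# A normalized small study: gene-level ratios plus metadata and sets.
small_study <- function(seed = 1, ...) {
  cfg <- small_config(seed, ...)
  coh <- generate_cohort(cfg)
  m <- summarize_exons(coh$exons)
  mm <- fit_marker_model(m, coh$meta)
  ratios <- normalize_log2ratio(m, mm)
  list(config = cfg, cohort = coh, gene = m, marker_model = mm,
       ratios = ratios, meta = coh$meta, sets = coh$sets,
       truth = coh$truth)
}

# A linearly separable toy feature table with n samples per class.
separable_features <- function(n = 10, p = 3, gap = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * p, sd = 0.3), 2 * n, p)
  x[seq_len(n), 1] <- x[seq_len(n), 1] + gap
  dimnames(x) <- list(sprintf("T%02d", seq_len(2 * n)),
                      sprintf("f%d", seq_len(p)))
  list(x = x, labels = rep(c("carrier", "non-carrier"), each = n))
}
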