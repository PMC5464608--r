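# icapr

Classifying disease from the transcriptional response of serum-exposed
indicator cells.

## The problem

An indicator-cell assay exposes standardized cultured cells — motor-neuron
embryoid bodies, iPSC-derived neurons — to patient serum or plasma, and
reads out the cells' global transcriptional response on expression arrays.
Because the cells integrate whatever disease signals circulate in blood, a
classifier trained on their response can act as a multicomponent blood-based
diagnostic, e.g. for pre-symptomatic ALS in a mutant-SOD1 mouse model or
early Alzheimer's disease from human plasma. `icapr` implements the complete
analysis chain for such assays, for computational biologists who want to
build, stress-test or audit this class of classifier:

1. **Input handling** — exon-level expression TSVs, GMT gene-set
   collections, sample metadata (`load_study()`); gene expression as the
   mean over each gene's exons (`summarize_exons()`).
2. **Array QC** — per-batch average inter-array Pearson correlations
   screened with an iterative two-sided Grubbs test (`qc_outliers()`).
3. **Batch normalization** — an OLS model of every target gene on four
   marker genes (defaults Olig2, Mnx1, Isl1, Lhx3), fit on reference
   (non-carrier) assays; expression becomes
   `log2(observed / predicted)` (`fit_marker_model()`,
   `normalize_log2ratio()`).
4. **Features** — per-gene Welch statistics (`differential_stats()`);
   gene-set scoring with the *maxmean* statistic
   `s = max(mean(z⁺), mean(z⁻))` (signed), restandardized against the
   observed gene-score catalog, with permutation p-values (`gsa_scores()`);
   aggregate set features (member-mean log2 ratios), filtered member genes,
   label-blind cluster features, a joint probability gene score, and a
   Sturges FWER bin filter.
5. **Shadow-feature selection** — every feature is duplicated as a permuted
   "shadow"; a random-forest (or fern) importance engine scores both, and
   `FWER(f)` = fraction of repetitions in which any shadow outranks `f`
   (`compute_fwer()`); features with FWER < 1 are ranked for the ensemble.
6. **The classifier** — a nested voting ensemble of N polynomial-kernel
   SVMs, where model *i* uses the top-*i* ranked features; class
   probability = votes/N (`icap_ensemble()`, with `predict`/`summary`
   methods), plus a CV-tuned single SVM (`train_tuned_svm()`) and clinical
   covariate fusion (`fuse_covariate()`).
7. **Active learning** — minimum-entropy ordering of a blinded test set
   using a Laplacian fitted on 3-fold cross-validated SVM residuals, with a
   hash-chained transcript proving each prediction was committed before its
   label was revealed (`active_loop()`).
8. **Evaluation** — the full confusion panel with exact binomial tail
   p-values (strictly-greater convention), MCC significance via the
   correlation t-test, vote-threshold ROC/AUC, BH q-values, LOOCV and
   repeated k-fold harnesses with all selection inside the fold, feature
   stability and hypergeometric enrichment (`confusion_metrics()`,
   `cv_harness()`, ...).

A seeded synthetic-cohort generator (`generate_cohort()`,
`generate_offsignature_cohort()`, `generate_validation_cohort()`) emulates
the statistical structure the analysis assumes — planted down-regulated
gene sets, batch effects linearly encoded in the marker genes, outlier
arrays, and an "off-signature" second-disease cohort — so every stage is
testable without external data.

## Worked example

```r
library(icapr)

cfg    <- synth_config(n_genes = 600, n_gene_sets = 30,
                       set_size_range = c(8, 14), n_responsive_sets = 6,
                       n_per_class = 12, n_batches = 4, seed = 7)
cohort <- generate_cohort(cfg)
expr   <- summarize_exons(cohort$exons)
model  <- fit_marker_model(expr, cohort$meta)
ratios <- normalize_log2ratio(expr, model)

diff <- differential_stats(ratios, cohort$meta)
gsa  <- gsa_scores(diff, cohort$sets, ratios, cohort$meta,
                   n_perm = 200, seed = 7)
gsa
#> Gene-set maxmean scores: 30 sets (restandardized, 200 permutations)
#>   selected: 6 down-only (score <= -1), 9 two-sided (|score| >= 1)

sel    <- select_sets(gsa, "down_only")
feats  <- aggregate_set_features(ratios, gsa$members[sel])
ranked <- compute_fwer(feats, cohort$meta$class,
                       n_trees = 500, n_reps = 50, seed = 7)
ens    <- icap_ensemble(feats, cohort$meta$class,
                        rank_for_ensemble(ranked), seed = 7)
ens
#> Nested SVM voting ensemble: N = 6 polynomial-kernel models (degree 3, cost 1)
#>   top features: SET007, SET017, SET010, SET027, SET022 ...

val  <- generate_validation_cohort(cfg, cohort$truth, n_per_class = 3)
vr   <- normalize_log2ratio(summarize_exons(val$exons), model)
pred <- predict(ens, aggregate_set_features(vr, gsa$members[sel]))
pred
#> Ensemble predictions for 6 sample(s) (N = 6 voters)
#>  sample_id votes probability   label
#>       V001     6           1 disease
#>       V002     6           1 disease
#>       V003     6           1 disease
#>       V004     0           0 control
#>       V005     0           0 control
#>       V006     0           0 control

confusion_metrics(pred$table$label, val$meta$class)
#> Confusion metrics (n = 6): TP 3 FP 0 TN 3 FN 0
#>   accuracy 1.000 (binomial p = 0), sens 1.000, spec 1.000
#>   FPR 0.000, FDR 0.000, F1 1.000, MCC 1.000 (p = 0)
```

The 6 gene sets selected here are exactly the 6 planted in
`cohort$truth$responsive_set_ids`: all six members of the nested ensemble
vote "disease" for every true carrier in the held-out cohort and "control"
for every non-carrier. The binomial p of 0 reflects the strictly-greater
tail convention at a perfect score (see `?binomial_pvalue_strict`).

`run_icap_config()` chains steps 4–8 behind a single configuration object,
and `run_icap_grid()` executes all 16 logical combinations of
{down-only vs two-sided selection} × {set vs gene features} ×
{shadow selection on/off} × {active learning on/off}, tallying how often an
off-signature cohort is correctly called non-carrier.

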