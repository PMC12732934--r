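# onsetomics

Transcriptomic analysis of age-of-onset effects in bipolar disorder (BD) and
schizophrenia (SCZ) postmortem brain cohorts, packaged as a reproducible,
fully synthetic-data-driven R pipeline.

## The scientific problem

In psychiatric case cohorts, an earlier age of illness onset marks a more
severe, possibly etiologically distinct subgroup. Given bulk RNA-seq from
postmortem dorsolateral prefrontal cortex of BD and SCZ donors, the
questions are:

1. Which genes change expression with age of onset, overall, within each
   sex, and specifically in BD versus SCZ (diagnosis x onset interaction)?
2. Do onset-associated genes organize into co-expression modules, and are
   those modules biology or cell-composition artifacts?
3. Can expression separate early-onset (< 18 years) from later-onset cases,
   and which genes carry that signal stably?
4. Do onset effects replicate in an independent cohort?

Real cohorts of this kind are controlled-access, so the package ships a
negative-binomial synthetic-cohort generator whose demographic margins
mirror a published 369-donor cohort (28.7% BD, 48.2% female, onset
22.1 +/- 8.2 years truncated to [7, 48], RIN 7.7 +/- 0.8, three library
batches), with planted effects whose ground truth is recorded in a truth
table. Every analysis claim in the package is tested against that truth.

## The model

Counts are simulated as `count_gi ~ NB(mean = 2^eta_gi * lib_i / 1e6,
size = 1/phi_g)` where the log2 linear predictor holds a gene baseline
(N(4, 1.5) log2 CPM), planted onset slopes (-0.05 log2/yr on a 40-gene
module, 30 female-specific genes, 30 BD-specific interaction genes), a
second 40-gene co-expression-only module, shared per-module latent factors,
four pseudo-cell-type marker factors, gene-specific batch offsets, and
N(0, 0.2) biological noise; dispersions are log-normal around 0.15.

The analysis chain:

- **Preprocessing** — CPM > 1 in >= 50% of samples filter, RIN < 6 and
  duplicate-donor exclusion, precision weights from a fitted mean-variance
  trend (lowess of sqrt residual SD on average log2 count, weight =
  predicted SD^-4), empirical-Bayes location-scale batch adjustment on
  log-CPM protecting the biological design, PCA batch diagnostics, VIFs.
- **Differential expression** — per-gene weighted least squares on
  `onset + diagnosis + age_death + sex + race + pmi + ph + rin` (SCZ
  reference), empirical-Bayes variance moderation (method of moments on
  log s^2), moderated t on augmented degrees of freedom, BH FDR;
  sex-stratified refits; interaction model with covariance-propagated
  BD-slope contrasts.
- **Enrichment** — preranked running-sum GSEA (hit weight |t|, miss
  1/(N-NH)) with a gene-label permutation null, sign-matched NES, empirical
  signed-pool FDR q; hypergeometric over-representation for discrete lists.
- **Co-expression** — signed adjacency ((1+r)/2)^beta with beta chosen as
  the smallest power reaching scale-free fit R^2 >= 0.80, topological
  overlap, average-linkage clustering with a static cut, minimum module
  size 30, eigengene merging below 0.25 dissimilarity, module-trait
  correlations; a BD-only network in parallel.
- **Cell composition** — PCA-based relative cell-type proportions from
  marker sets, overlap and association tests, and a sensitivity refit that
  reports onset-slope attenuation (never auto-applied).
- **Early-onset classifier** — onset < 18 dichotomy, repeated stratified
  nested CV (5 outer folds x 10 repeats = 50 folds; inner 5-fold x 3
  repeats), stage 1 LASSO on continuous onset for feature selection, stage
  2 ridge logistic on the selected genes, rank AUC, per-gene selection
  stability, and a programmatic leakage audit of the recorded fold ledger.
- **Meta-analysis** — BD-specific slopes combined with an independent
  array-like 40-sample BD cohort by Fisher's method and a signed
  sqrt(n)-weighted Stouffer Z; the high-confidence set needs both BH FDRs
  < 0.05 plus sign concordance.

## Worked example

```r
library(onsetomics)
res <- run_pipeline(default_run_config(seed = 1))
```

With the default desk-scale configuration (300 samples x 2,000 genes,
planted slope -0.05 log2/yr) this prints nothing but returns every stage;
the headline numbers for seed 1 are:

```r
res$preprocess$n_genes_kept          # 1997 genes survive the CPM filter
ncol(res$preprocess$expr$E)          # 297 samples (3 excluded for RIN < 6)
res$preprocess$pca_pre$batch_r2[1]   # 0.996  PC1 batch R^2 before correction
res$preprocess$pca_post$batch_r2[1]  # 0.004  and after
head(res$dge$primary, 3)
#   gene    slope      t        p          fdr
# g00015  -0.0579  -11.01  4.7e-24  9.4e-21   <- planted onset-module gene
# g00013  -0.0574  -10.57  1.5e-22  1.5e-19
# g00005  -0.0504  -10.02  1.1e-20  7.6e-18
res$gsea[1, c("set", "es", "nes", "q")]
# onset_module  es -0.999  nes -3.04  q 0
res$network$modules$power            # soft power 12
length(res$network$modules$sizes)    # 20 modules
res$classifier$report$mean_auc       # 0.843 over 50 outer folds
length(res$classifier$stability$always)  # 7 genes selected in every fold
length(res$meta$high_confidence)     # 53 replicated high-confidence genes
```

All 40 planted onset-module genes reach FDR < 0.05, the two planted
co-expression blocks come back as two clean modules (adjusted Rand index 1.0
on the planted genes), the onset module's eigengene correlates -0.70 with
onset, and the 53-gene high-confidence meta list overlaps the 70 truly
shared genes at hypergeometric p ~ 1e-86.

## Known limitations

- One signal-recovery assertion, mean outer AUC >= 0.9 for the early-onset
  classifier, is **not attainable** under the generator's a-priori noise
  calibration and is left failing rather than weakened: an in-sample oracle
  regression given the true planted genes only reaches AUC ~0.93, and honest
  nested cross-validation reaches ~0.83-0.87 across seeds. The classifier
  implementation itself reaches AUC ~0.96 when the planted slope is tripled,
  so the gap is information-theoretic, not a code defect.
- The batch adjuster is an empirical-Bayes location-scale model on log-CPM
  (not a count-level model); module detection uses a static dendrogram cut
  (not hybrid dynamic tree cut); both deviations are recorded in the run
  manifest.
- The synthetic generator plants log-linear onset effects with Gaussian
  latent factors; it does not model zero inflation, GC/length bias, or
  donor-level random effects.

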