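---
title: "Methods: models, numerical choices, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerical choices, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(onsetomics)
```

This vignette documents the statistical models implemented in `onsetomics`,
the parameters of the synthetic data generator, the numerical choices made
where several defensible options existed, and the places where the analysis
chain deliberately deviates from the reference tools it is cross-checked
against. Code chunks are illustrative and not evaluated when the package is
built; the full pipeline at the default configuration runs in about a
minute (see the README for a worked example with printed numbers).

## 1. The scientific setting

The package studies age of illness onset in postmortem brain transcriptomes
from donors with schizophrenia and bipolar disorder. The working hypothesis
is that earlier onset leaves a detectable molecular trace: genes whose
cortical expression co-varies with onset age, co-expression modules whose
summary expression tracks onset, and enough multivariate signal to classify
early- versus late-onset donors above chance. Because no public dataset
pairs all the required annotations with ground truth, the package ships a
calibrated synthetic-cohort generator and treats recovery of planted
effects as the test of the analysis chain.

## 2. The synthetic cohort generator

### 2.1 Count model

Counts are drawn from a negative binomial observation model on top of a
log-scale linear predictor:

- each gene g has a baseline abundance `alpha_g` (log2 CPM scale) drawn from
  a mixture that reproduces the long right tail of bulk RNA-seq, and a
  dispersion `phi_g` decreasing with abundance (around 0.15 at moderate
  expression), matching the mean–dispersion trend of bulk brain data;
- sample-level library sizes are log-normal around 30 million;
- a per-gene, per-sample biological noise term (sd 0.2 on log2) sits on top
  of the NB sampling noise, so technical replicates are *not* the only
  variance source;
- batch enters as a log-scale location shift per batch plus a mild scale
  effect, so the batch correction step has realistic work to do;
- cell-type marker blocks (4 types x 20 markers) share a latent abundance
  factor per sample, giving the deconvolution module a recoverable target.

`cohort_spec()` fixes the demographic margins (diagnosis by sex, onset-age
distribution with mean ~22 and sd ~8, age at death, PMI, pH, RIN, batches)
to the published cohort this design mirrors; `effect_plan()` fixes what is
planted:

- an *onset module*: 40 genes sharing a latent factor (sd 0.4 on log2) whose
  loading also carries a common onset slope of -0.05 log2 CPM per year;
- a *pure co-expression module*: 40 genes sharing a factor but with no
  onset association (a specificity control for the network module);
- 30 *female-specific* genes whose onset slope exists only in female donors;
- 30 *diagnosis-interaction* genes whose onset slope exists only in bipolar
  donors;
- everything else is null.

All planted identities, slopes, and block memberships are returned in a
truth table (`truth_table()`), which the tests and the acceptance suite use
as the only source of ground truth.

### 2.2 Realism and limits

The generator is calibrated to first and second moments of real bulk brain
RNA-seq (abundance distribution, dispersion trend, library-size spread,
batch effect sizes that explain most of PC1 before correction). It does
*not* model: gene–gene correlation beyond the planted blocks and marker
blocks, GC/length biases, isoform structure, RNA-degradation gradients
beyond a scalar RIN covariate, or cell-type proportion shifts correlated
with diagnosis. Conclusions about the *analysis chain* transfer; absolute
effect-size or power numbers should not be read as field estimates.

The generator's parameters — including the planted slope of -0.05 — are the
study conditions. They were fixed before any recovery results were
inspected and are not tuned so that downstream assertions pass; the README
documents one consequence of that policy (an out-of-sample AUC target that
sits above the information ceiling at this slope and noise level).

### 2.3 Problem sizes

The default configuration (`default_run_config()`) analyzes 300 samples by
2,000 genes. These sizes are this package's own choice: large enough that
empirical-Bayes moderation, soft-threshold selection, module detection and
nested cross-validation all operate in their intended regimes, and small
enough that the full pipeline plus the test suite run on one CPU well
inside a CI budget. The second, replication cohort is 40 samples — small on
purpose, so the meta-analysis has to combine a well-powered and a
marginally powered study.

## 3. The analysis chain, stage by stage

### 3.1 Preprocessing

`exclude_samples()` drops flagged duplicate donors and low-RIN samples.
`filter_low_expression()` keeps genes with CPM > 1 in at least half the
samples. `voom_weights()` implements the mean–variance precision-weight
idea: log2-CPM transform, lowess fit of sqrt residual sd against average
log-count, inverse predicted variance as observation weights. It is
cross-checked against `limma::voom` (identical `E`, weights correlated at
~1).

`correct_batch()` is an empirical-Bayes location–scale batch adjuster on
the log2-CPM matrix with covariate protection: batch effects are estimated
after projecting out the protected design (so planted onset slopes
survive), then shrunk toward the across-batch mean before removal. With
`shrink = FALSE` it reduces exactly to per-batch centering and scaling,
which is what its unit tests pin down; with shrinkage it agrees with
`sva::ComBat` to within numerical noise (correlation > 0.9999). The reason
it is implemented here rather than delegated is precisely that exposed
limiting behaviour, which ComBat does not offer.

**Deviation (EB on log-CPM):** batch adjustment operates on the log2-CPM
matrix rather than on counts. A count-level adjustment would require
refitting the NB model per batch; the log-scale EB adjustment composes
cleanly with the precision weights and is standard practice downstream of
a voom-style transform.

`compute_vif()` and `pca_batch_check()` provide the design diagnostics:
variance-inflation factors for the covariates (closed form `1 / (1 - R^2)`)
and the variance in PC1 explained by batch before and after correction.

### 3.2 Differential expression

`fit_gene_models()` fits per-gene weighted least squares (QR-based, checked
against explicit normal equations at 1e-8). `moderate_and_test()` applies
empirical-Bayes variance moderation: the prior degrees of freedom and prior
variance are estimated from the spread of log residual variances by a
method-of-moments fit on the log scale (`trigamma_inverse` for the df, a
digamma/log bias correction for the scale); posterior variances are the
usual df-weighted mix, and moderated t statistics use `df + d0` degrees of
freedom, capped at the pooled residual df across genes (shrinkage cannot
add more information than the data pool contains). When the observed log-variances show no excess spread beyond chi-square
sampling noise the prior df is infinite and every gene shrinks fully to the
mean sample variance. The whole path is cross-checked against
`limma::eBayes` to 1e-6.

Three models are fit: *primary* (onset + diagnosis + sex + covariates),
*interaction* (adds onset x diagnosis; `interaction_slopes()` propagates
the coefficient covariance to get the bipolar-specific slope and its SE),
and *sex-stratified* (`stratified_fit()`, the sex term dropped within a
stratum).

**Open choice (weights in DGE):** the precision weights from
`voom_weights()` are used by default in all gene-level fits. The
alternative — unweighted fits on the corrected matrix — is supported
(`elist(E)` without weights) but non-default, because the generator's
mean–variance trend is real and ignoring it costs calibration at the
low-abundance end.

### 3.3 Gene-set enrichment

`gsea_preranked()` implements the weighted Kolmogorov–Smirnov running-sum
statistic (exponent 1) with a gene-permutation null, normalized enrichment
scores, and sign-aware q-values. The running sum is cross-checked two ways:
against `fgsea::calcGseaStat` (1e-10) and against an exhaustive
walk-the-ranking oracle on every subset of small universes. When the
positive and negative extremes of the walk tie to floating-point precision
the reported sign is a convention; the magnitude is what is defined.

**Open choice (ranking statistic):** genes are ranked by the moderated t
statistic rather than by slope or -log p x sign. The moderated t combines
effect size and precision in one number and is monotone in p within a sign,
which is the behaviour the permutation null assumes.

**Deviation (internal ORA):** over-representation analysis
(`ora_hypergeometric()`, `ora_collection()`) is implemented on
`stats::phyper` directly rather than through an annotation package, since
the gene universes here are the package's own synthetic identifiers.

### 3.4 Co-expression network

`build_network()` follows the signed weighted-network recipe: signed
adjacency `((1 + r) / 2)^beta`, soft threshold `beta` chosen by
`pick_soft_threshold()` as the smallest power reaching the scale-free fit
target (with a connectivity fallback), topological overlap
(`topological_overlap()`, checked against the direct elementwise formula),
average-linkage hierarchical clustering on TOM dissimilarity, and
`merge_modules()` merging modules whose eigengenes correlate above the
merge threshold. `module_eigengene()` is the first right singular vector of
the standardized module submatrix, sign-aligned to positive mean
correlation with its genes.

**Deviation (static tree cut):** modules are defined by a static cut of the
dendrogram at a fixed height plus a minimum module size, rather than the
dynamic hybrid cut used by WGCNA. The dynamic cut's advantages matter most
for real transcriptome-scale networks with nested module structure; at
this problem size the static cut recovers the planted blocks exactly and
keeps the implementation auditable. Genes in undersized clusters fall back
to an unassigned ("grey") label.

### 3.5 Cell-type deconvolution

`estimate_rctp()` computes relative cell-type proportions as the first
principal component of each marker set's standardized expression,
sign-aligned and z-scored. `rctp_module_association()` flags modules whose
eigengenes track composition rather than intrinsic biology, and
`rctp_sensitivity()` refits the primary DGE model with rCTPs as covariates
and reports the attenuation of each onset slope.

### 3.6 Onset classifier

`dichotomize_onset()` applies the strict early-onset cut (< 18 years).
`nested_cv()` runs stratified 5-fold outer cross-validation repeated 10
times (50 outer folds). Inside each outer training fold, `inner_tune()`
selects the two-stage model by inner CV: stage 1 is a LASSO-logistic scan
whose active set at the inner-CV-optimal lambda defines the features;
stage 2 is a ridge-logistic fit on those features. All tuning, feature
selection, and any fold-local preprocessing happen strictly inside the
outer training fold; `audit_leakage()` re-checks the recorded fold ledger
(disjoint train/test, each repeat's test folds partition the samples).

**Open choices:** inner folds are 5 x 3 repeats — enough to stabilize the
lambda choice without dominating runtime; stage-1 features are taken at the
inner-CV-optimal lambda itself (not the 1-SE rule), because with 2,000
candidate genes and a planted 40-gene module the 1-SE rule is too
aggressive and hurts the stability tiers that downstream reporting relies
on. Feature stability (`feature_stability()`) reports genes selected in
all folds and in at least half the folds.

### 3.7 Replication meta-analysis

`second_cohort_dge()` analyzes the small replication cohort with the same
per-gene model. `meta_analyze()` combines the two cohorts per shared gene
by Fisher's method (chi-squared with 4 df on -2 sum log p) and by signed
Stouffer with sqrt(n) weights (z from two-sided p and the slope sign).
`high_confidence_set()` requires both combined FDRs below threshold plus
sign concordance, sorted by |Z|. Both combiners are pinned to closed forms
in the tests.

### 3.8 Orchestration

`run_pipeline(default_run_config(seed = ...))` runs the stages in order
with per-stage seeds derived from the master seed via `derive_seed()`
(SHA-based, so stages are decoupled), and returns every intermediate
object. `read_run_config()` round-trips the configuration through YAML;
`write_outputs()` writes the main tables as TSV with an MD5 manifest. A
thin command-line wrapper lives at `system.file("cli", "onsetomics.R",
package = "onsetomics")`.

## 4. Verification strategy

Every nontrivial statistic has at least one independent route in the test
suite: brute-force oracles (normal equations, exhaustive GSEA walk,
pairwise-concordance AUC, elementwise TOM, closed-form Fisher/Stouffer/
hypergeometric), established packages as cross-checks (limma, sva, fgsea,
mclust — Suggests only, never in the analysis path), calibration tests on
all-null cohorts (uniform p-values, near-zero FDR call rates, chance-level
permuted-label AUC), and end-to-end recovery of the planted truth at the
default study conditions. The acceptance script
(`scripts/acceptance.R --seed <int> --out <path>`) re-runs the full
pipeline plus the null-calibration battery from a single seed and writes
the headline quantities as JSON.
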