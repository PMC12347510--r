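---
title: "Discovering wound-healing and fibrosis gene signatures with fibrosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering wound-healing and fibrosis gene signatures with fibrosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After cataract surgery, residual lens epithelial cells either re-heal the
denuded capsule (regenerative wound healing, WH) or transform into
myofibroblasts that deposit fibrotic matrix (fibrosis, F) — the process
behind posterior capsule opacification. Ex vivo lens explant models
produce paired WH and F cell populations over the first days after
injury, and bulk RNA-seq of those populations yields a classic
small-n / large-p problem: a handful of samples (two conditions, three
days, three biological replicates — 18 samples) against ~10⁴ genes,
from which one wants a small, robust gene panel that discriminates the
two outcomes.

`fibrosig` implements the full analysis as a reusable, tested pipeline:
normalization, univariate screening, three supervised feature-selection
tracks, held-out evaluation, per-candidate-gene set enrichment, and
ΔΔCt qPCR quantification, plus a synthetic-data generator that emulates
the design so every stage is testable without any external download.

## Data model and normalization

Expression arrives as a gene × sample FPKM table plus sample metadata
(`condition` ∈ {WH, F}, `day` ∈ {1, 2, 3}). `fpkm_to_tpm()` converts to
TPM,

$$\mathrm{TPM}_{g,s} = \frac{\mathrm{FPKM}_{g,s}}{\sum_{g'} \mathrm{FPKM}_{g',s}} \times 10^6,$$

which normalizes depth on top of FPKM's length correction and forces
every sample column to sum to 10⁶ — an invariant the tests assert to a
relative 10⁻⁶. Modeling happens on `log2(TPM + 1)`: base 2 because all
fold changes downstream are log2, offset 1 because it stabilizes
variance while keeping zeros at zero. The offset is a parameter
everywhere it is used. Two scales deliberately coexist: TPM-derived
values drive screening and modeling, while pooled fold changes for
reporting are computed from the original FPKM values, mirroring common
practice of modeling on one normalization and visualizing on the
provider's original units.

`make_holdout_split()` reserves five samples per class (configurable)
for final evaluation. The draw is stratified by condition only: five
per class cannot be balanced across three days of three replicates, so
day balance is left to chance and the seed is recorded. Everything
downstream of the split — screening included — sees training samples
only; the holdout enters exclusively at evaluation time, and the
pipeline's tests assert the partition.

## Univariate screen

`screen_genes()` keeps a gene when both (i) the absolute difference
between its WH and F mean TPM values is at least `diff_threshold`
(default 1, on the literal TPM scale) and (ii) a two-sided Welch test
yields p ≤ `alpha` (default 0.05). The Welch test runs on
`log2(TPM + 1)` by default — the variance-stabilized scale — while the
mean-difference criterion uses raw TPM; both scales are switchable,
since a difference of one TPM is a deliberately weak magnitude filter
and some analyses will prefer a log-scale threshold. No multiplicity
correction is applied at this stage: the screen is a pre-filter for the
supervised models, not an inference procedure. Genes with zero variance
in both conditions have no defined statistic; they are dropped with a
warning rather than silently kept. The row-wise Welch implementation is
vectorized and is tested gene-by-gene against `stats::t.test`.

## Three selection tracks

All tracks code fibrosis as the positive class and work on z-scored
training genes; rankings break ties by gene id so results are
reproducible to the byte under a fixed seed.

**Bootstrap-LASSO stability selection.** `stability_select()` draws 200
stratified subsamples of 75% of the training samples without
replacement; in each it z-scores genes on the subsample and fits an
L1-penalized logistic regression (via glmnet) at a penalty chosen by a
fast 3-fold stratified cross-validation over a shared grid of 100
log-spaced values from λ_max (the smallest empty-support penalty on the
full training data) down to λ_max·10⁻³. If cross-validation degenerates
the iteration falls back to λ_max/10. A gene's selection frequency is
the fraction of iterations in which it received a nonzero coefficient;
genes at frequency ≥ 0.5 form the stable set. `cv_refit()` then picks
the penalty minimizing 3-fold cross-validated binomial deviance over
the stable genes alone and refits on all training samples; genes with
nonzero coefficients in that refit are the final LASSO panel. When the
stable set has a single gene a zero dummy column is padded in (the
solver requires two columns) and dropped from the reported model.

**Linear-SVM ranking with permutation pruning.** `rank_linear_svm()`
fits one linear soft-margin SVM (C = 1, fixed rather than tuned) and
ranks genes by |w|. The top five are audited by
`svm_permutation_importance()`: out-of-fold AUC over three stratified
training folds is the baseline, each gene's values are shuffled across
samples 100 times, fold models re-score without refitting, and the
importance is the mean AUC drop. Genes with non-positive drop are
pruned. `fit_calibrated_rbf()` trains an RBF-kernel SVM
(γ = 1/(d · mean feature variance), C = 1) on the surviving panel and
calibrates probabilities by Platt scaling — a binomial GLM on
out-of-fold decision values; with eight training samples isotonic
calibration is infeasible. Decision values are oriented so positive
means wound healing and negative means fibrosis.

**Random forest.** `fit_rf()` grows 500 trees sampling 50% of genes at
each split and ranks genes by mean decrease in Gini impurity,
normalized to sum to one. `confirm_and_reduce()` computes the same
out-of-fold permutation importance for the top ten, keeps the top three
by Gini among genes with strictly positive importance, and refits a
reduced forest on that panel; its probability for a sample is the
fraction of trees voting fibrosis.

A behavior worth knowing: permutation importance can be *exactly zero*
for genuinely informative genes. When several genes carry redundant
signal, or when out-of-fold probabilities are saturated, shuffling one
gene never reorders the handful of training samples and the AUC never
moves. The pruning rule (strictly positive drop) then shrinks — possibly
empties — a panel. The pipeline logs and tolerates this; the retention
threshold is a parameter for analyses that prefer `≥ 0`.

## Evaluation

`auc_score()` is the Mann–Whitney midrank statistic — the probability a
fibrosis sample outscores a wound-healing one, ties counted half — and
is tested for exact agreement with an all-pairs enumeration oracle.
`confusion_and_pr()` assembles ROC and precision–recall curves, the
2×2 confusion matrix (rows truth, columns prediction) and accuracy at a
0.5 probability threshold. `per_gene_roc()` scores one gene's
expression as a classifier, reporting max(AUC, 1−AUC) with an
orientation flag, since a marker is useful in either direction. With
five holdout samples per class the AUC grid is 1/25 = 0.04; single-gene
AUCs should be read at that granularity. `pooled_log2fc()` reports
log2(mean F / mean WH) over all nine samples per condition on the FPKM
scale, with a Welch test and 95% t confidence intervals on
log2(FPKM + 1); when a pooled mean is exactly zero the offset is added
inside the ratio and the record flagged, avoiding infinities without
disturbing typical values. `pca_projection()` provides the standard
mean-centered sample PCA for QC.

## Per-candidate-gene enrichment

For each selected gene, the transcriptome is ranked by Pearson
correlation with that candidate across all samples — the common idiom
for "per-gene" enrichment when there is no second phenotype to rank by;
the ranking metric is a parameter. `enrichment_score()` computes the
weighted Kolmogorov–Smirnov running sum: hits add
|metric|^p / (sum over set hits), misses subtract 1/(N − N_hits), so the
walk always ends at zero (asserted to 10⁻⁹) and the enrichment score ES
is the extremum of largest magnitude; the leading edge is the set
members at or before the extremum (at or after, for negative ES).
`nes_and_fdr()` normalizes against nulls built from random same-size
gene sets — phenotype permutation is meaningless at n = 18 — with
NES = ES / mean(|null ES| of the same sign) and an FDR from the pooled
null-to-observed tail ratio, capped to [0, 1]. Results are filtered to
NES > 0 and sorted by FDR, matching the positive-enrichment reporting
convention for candidate biomarkers. Gene sets load from standard GMT
files (via `fgsea::gmtPathways`); set sizes outside [5, 500] after
intersection are skipped.

## qPCR quantification

`ddct_analysis()` implements the ΔΔCt method: technical replicates are
averaged to one Ct per (experiment, condition, gene);
ΔCt = Ct_target − Ct_reference (GAPDH by default); the second
difference is taken *within experiment* against the baseline condition,
so the baseline's fold change is exactly 1 and any plate-wide Ct shift
cancels exactly — both properties are asserted in the tests. Fold
changes are 2^−ΔΔCt (amplification efficiency fixed at 2, the method's
standard assumption; no standard-curve correction). Per gene the mean
fold and SEM over the biological replicates are reported alongside a
two-sided Welch test comparing the conditions' ΔCt values — testing on
ΔCt rather than on folds keeps the test on the scale where the noise is
approximately Gaussian.

## The synthetic-data generator

`generate_expression()` emulates the study design: per gene a baseline
log2 mean drawn uniformly from [0, 10]; planted genes (defaults: 20
fibrosis-associated, 10 wound-healing-associated) shifted by the effect
size (default 3 log2 units) in their condition; mean-zero per-gene,
per-day nuisance shifts (SD 0.25) shared by both conditions, since the
analysis pools days; Gaussian log2 noise (SD 1); back-transformation to
a linear scale and per-sample log-normal library factors (CV 0.1),
which TPM conversion must undo. Defaults are chosen once to represent a
strong-but-noisy transcriptomic signature at this design size.
Companion generators emit GMT gene sets (a planted set containing the
fibrosis-planted genes plus size-matched random sets) and Ct tables
(Ct = a − log2(expression) + N(0, 0.1), constant reference), so the
enrichment and qPCR modules can be exercised end to end with known
truth.

What the generator does *not* emulate matters for interpreting green
tests: real RNA-seq has heavy-tailed count noise, correlated gene
modules, trending (not mean-zero) day effects, and batch structure.
Passing recovery tests here demonstrates that the machinery is correct
and well-calibrated, not that an 18-sample experiment reliably recovers
any particular real signature.

## Numerical choices and degenerate inputs

* Tie-breaks: all rankings order by score then gene id; stable-set
  ordering is frequency then id.
* Zero-variance genes: excluded per bootstrap (cannot be z-scored),
  scored 0 by the correlation ranking, flagged at importance 0, AUC 0.5
  for per-gene ROC.
* Subsamples drawn per class with ⌈fraction · n_class⌉, retried if a
  class is lost (bounded retries).
* Calibration folds collapse to one class → folds are reduced with a
  warning; below two folds is an error.
* Empty screens, empty stable sets and empty panels are explicit
  errors or logged shrinkages, never silent.

## Problem sizes used by the test suite

Module tests run on 100–300-gene simulations; calibration and recovery
properties use 2000 genes at the full 18-sample design over 20 fixed
seeds; the held-out evaluation checks use the standard 5-per-class
split. Recovery properties are deliberately evaluated at the full
design rather than on the eight training samples of the split: with
four samples per class, essentially every screened gene separates the
training set in-sample, in-sample impurity and margins saturate, and no
selector can distinguish planted from lucky-noise genes — an intrinsic
small-n limit, not an implementation artifact. At the full design the
selectors place planted genes at the top of their rankings in the large
majority of seeds, while selection frequencies split across mutually
correlated planted genes (the LASSO picks subsets of redundant
predictors), which caps per-gene stability frequencies well below 1.

## Known limitations

* With eight training samples, feature selection is inherently
  unstable; different tracks legitimately return largely disjoint
  panels, and holdout metrics on ten samples have coarse granularity.
* Stability frequencies are not comparable across datasets with
  different redundancy among true predictors.
* Gene-set-permutation FDRs are liberal relative to phenotype
  permutation when genes are co-expressed; they are the only option at
  this n.
* The ΔΔCt model assumes perfect doubling per cycle and a stable
  reference gene; neither is checked from the data.
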