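---
title: "Models and methods behind nmrconfound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmrconfound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the synthetic cohort generator does and does not emulate, and the
numerical and design choices made where more than one convention exists.

## The data and its confounding structure

The unit of analysis is a peak table: samples in rows, NMR peaks in
columns, each peak labelled by its chemical shift (a 3-decimal ppm string
such as `"2.356"`). A cell is either a nonnegative intensity or a
*non-detect* — a signal below the detection limit, stored as `NA` and kept
distinct from a measured zero throughout. Sample metadata carries the
design: role (STUDY patient, QC pool replicate, healthy-volunteer
reference), disease group (PHT control vs the endocrine-hypertension
forms PA, PPGL, CS), center of origin, center cluster, sample age in days
(time from blood draw to NMR acquisition), analytical batch and run order,
sex and patient age.

The scientific difficulty is that center of origin and sample age are
strong sources of variation. Centers differing in pre-centrifugation and
pre-storage handling separate into two clusters along the first principal
component, with opposite shifts on a reproducible 14-metabolite panel
(`table4_template()`): prolonged contact with red blood cells raises
lactate, glutamate, ornithine and glycerol and depletes glucose, pyruvate
and glutamine; long frozen storage acts on an overlapping panel. Because
disease groups are unevenly represented across centers, these shifts are
*confounders*: a supervised model can separate diagnoses by learning
center chemistry.

## Preprocessing chain

The chain runs in a fixed order (observable in the report):
peak exclusion → presence filter → quotient normalization → QC CV filter →
imputation → generalized log → optional outlier pass with a re-run.

* **Presence filter** (`presence_threshold = 0.80`): a peak is kept iff
  detected in at least 80% of QC samples *or* 80% of HV samples. The OR
  reflects that either reference group suffices to establish a peak as
  reliably measurable.
* **Probabilistic quotient normalization**: the reference spectrum is the
  per-peak median over a designated healthy-volunteer pool (ignoring
  non-detects); each sample is divided by the median of its detected
  quotients against that reference. After normalization the median
  quotient of every sample against the original reference is exactly 1 —
  a machine-precision identity the tests assert. QC samples are
  normalized against the same HV reference, never against study-sample
  factors.
* **CV filter** (`cv_threshold = 0.30`): peaks whose sd/mean over detected
  QC replicate values exceeds 30% are removed; peaks with fewer than three
  detected QC values are removed as unsupported (a conservative reading).
  The filter runs after normalization, its position in the stated order;
  a pre-normalization variant sits behind `cv_before_pqn = TRUE`.
* **k-NN imputation** (`knn_k = 10`): each non-detect is replaced by the
  1/distance-weighted mean of the peak's detected values in the k nearest
  samples. Distance is the root-mean-square difference over mutually
  detected peaks, so samples with different amounts of missingness are
  comparable; exact duplicates (distance 0) take over entirely;
  neighbours lacking the target peak are skipped for the next nearest.
  `k >= n` is clipped to `n − 1` with a warning. The test suite holds this
  implementation equal to an exhaustive-search oracle over random small
  matrices.
* **Generalized log** `g(x) = ln(x + sqrt(x^2 + lambda))`: at λ = 0 it is
  `ln(2x)`; for large λ it is affine. λ is fitted on QC replicates by a
  grid search (25 log-spaced points over 1e−2…1e8) minimizing the variance
  of the per-peak replicate variances *divided by their mean*. The
  division makes the criterion scale-free; without it the raw
  variance-of-variances is trivially minimized by λ → ∞, which flattens
  the transform and the criterion with it. The scale-free form also makes
  the natural invariance exact: scaling all intensities by c rescales the
  fitted λ by c². This criterion is a deliberate, simpler stand-in for the
  maximum-likelihood fit described with the original transform; both
  stabilize QC technical variance, which is all downstream mean-centered
  modelling needs.
* **Outlier pass**: each reference group (QC, HV) is screened by PCA on
  median-centered, MAD-scaled data; samples whose score distance (against
  the χ² 0.975 quantile at the retained rank) or orthogonal distance
  (against the normal-quantile cutoff on OD^{2/3}) is excessive are
  flagged, and the normalization reference and λ are re-estimated without
  them. Groups under 10 samples are skipped with a warning. STUDY samples
  are never dropped by preprocessing.

## PLS-DA, sparsity, VIP, prediction

Classes enter as a centered indicator column per class (also for two
classes, so binary and multiclass runs share one code path). Data are
mean-centered and *not* scaled — metabolite intensities share a common
(log) scale after the transform. Per component, the weight vector is the
dominant left singular vector of X'Y; X is deflated by the score-loading
outer product, Y is left undeflated (the most common convention; the
acceptance properties are convention-invariant). The component sign is
fixed by making the largest-magnitude weight entry positive, so fits are
byte-reproducible across platforms. The sparse variant truncates each
weight vector to its `keepX` largest-magnitude entries and renormalizes
before scoring; `keepX = p` reproduces the dense model exactly, and
features never selected carry exact zero regression coefficients.

VIP scores use the explained-Y sum of squares per component as weights;
mean VIP² over features is identically 1, so VIP > 1 marks
above-average influence. Class prediction projects new samples into score
space (via W(P'W)⁻¹) and assigns the class with the smallest Mahalanobis
distance to the class score mean under the pooled within-class score
covariance (denominator n − g; ridge ε = 1e−8·trace/A on singularity,
with a warning). Ties break to the first class in sorted label order
(CS < PA < PHT < PPGL).

## Double cross-validation

Model size must be chosen and performance estimated without reusing the
same held-out data for both, hence two nested loops: stratified outer
folds (k = 8, 50 repeats, folds re-randomized each repeat) estimate
prediction performance; within each outer-training set a single stratified
inner pass (k = 7) scores every candidate size. Contrasts with higher
class imbalance use smaller k (7/6 for CS-vs-PHT, 6/5 for the reduced
center-filtered cohorts). Metrics are reported on the percent scale as
mean with a one-sample-t 95% confidence interval across outer repeats;
balanced accuracy is the mean of per-class true-positive rates.

**Model-size selection.** The inner criterion is overall accuracy. The
package selects the *smallest* model (fewest components, then fewest
variables) within one binomial standard error of the maximum inner
accuracy (`cv_config(se_tol = 1)`; 0 restores the strict
minimum-at-maximum rule). The tolerance matters under the null: with a
strict argmax, inner accuracy is noise and the selected size is close to
uniform over the grid, so even pure-noise data frequently ends with large
models; with the one-SE rule, noise-level differences cannot justify a
larger model and null runs collapse to the smallest sizes. Signal-driven
selection is unaffected because real accuracy gains exceed one SE.

**Signatures.** Two extraction rules are provided: features whose median
VIP across all outer-fold refit models exceeds 1 (strict inequality), and
sparse PLS-DA coefficients from a final all-sample fit whose size is the
modal choice over repeated single CV (ties to the smaller size). Two
conventions are worth stating: the outer 50 repeats re-randomize folds
each repeat, and VIPs are taken from the models refit on each
outer-training set (not from inner-loop winners).

**Degenerate folds.** If a training fold retains no class covariance at
all (this happens by construction when the factor being classified has
just been residualized away), the fold falls back to a null model
predicting the majority training label — the honest chance-level answer —
rather than erroring out.

## Confounder corrections

**A — residualization.** ASCA decomposes the centered matrix into
per-factor effect matrices (level means of the centered data), an
optional interaction (cell means minus main effects) and residuals; the
reconstruction is exact and, in balanced designs, the effect matrices are
mutually orthogonal. Correction subtracts chosen effects (default: the
cluster main effect, plus the cluster-by-disease interaction when every
cell is populated — with no CS samples in cluster 1 the interaction is
not estimable, and the decomposition fails naming the empty cell).

One subtlety is load-bearing: *when* the correction happens. Removing a
factor's level means from the full matrix forces the held-out samples'
group means to be exactly anti-correlated with the training means inside
any subsequent cross-validation, which drives the removed factor's
apparent accuracy far *below* chance (anti-learning) — a measured ~10%
balanced accuracy where 50% is the truthful answer. `cv2_evaluate()`
therefore accepts a fold-internal correction: the decomposition is
estimated on each outer-training fold and applied out-of-sample to the
held-out fold through the training level means (`asca_correct_oos()`).
Signatures are still extracted from the once-corrected full matrix, as is
conventional.

**B — peak exclusion.** Three probes build the exclusion list: PLS-DA
under double CV on the cluster grouping (cluster 1 minus the flagged
FRPA1-PHT subgroup vs cluster 2), the same on sample age dichotomized at
the global median over all STUDY samples, and — for the small flagged
FRPA1-PHT subgroup — the PCA component correlating most with the flag,
returning peaks with |component correlation| > 0.5 (empty, with a
warning, when no component reaches |r| > 0.3). Two design choices:

* A VIP list is only extracted when the confounder grouping is actually
  learnable (mean CV2 balanced accuracy ≥ 60%). About a third of the
  entries of a random unit weight vector exceed VIP 1, so an unpredictive
  model would always "find" a signature; the gate returns an empty list
  instead.
* The probe is *iterated*: found peaks are excluded, the reduced matrix is
  probed again, and the loop stops when the groupings stop being
  learnable (or after `max_iter = 4` rounds). VIP ranks features relative
  to one another, so a single pass hides weaker confounder peaks behind
  stronger ones; the goal of this approach is an inclusive list of all
  related peaks, not the most predictive subset. A peak-to-metabolite
  namespace optionally expands any hit to all peaks of that metabolite,
  the way the exclusion list is organized per metabolite.

**C — center exclusion.** Only the tight-cluster centers are retained;
the scenario is evaluated by double CV on the retained subset, and a
model with the modal CV2 hyperparameters refit on all retained samples
predicts every excluded STUDY sample of the scenario's classes (external
accuracy, sensitivity, specificity). Retained-cohort bookkeeping drops
disease groups that fall below `min_per_group = 5` retained samples — a
handful of samples cannot support a classification contrast, which is why
the retained cohort of the study layout has no Cushing group (4 CS
samples fall in the retained centers) and counts 118 EHT = 54 PA + 64
PPGL patients against 40 PHT.

## The synthetic cohort generator

Intensities are log-normal with additive structure on the log scale:
baseline per peak, disease shifts on configurable peak sets, the cluster-2
template shift (`cluster_effect_scale`, default 0.5 log units — chosen to
reproduce the qualitative cluster separation along PC1, not any printed
variance percentage), a delayed-storage sub-template (glutamate up,
glutamine down, no glycolysis shift) for the flagged FRPA1-PHT subgroup,
a sample-age slope (0.15 log units per 1000 days on the template peaks,
signed by the template), batch offsets (sd 0.05), a run-order drift
(0.002 per position) and residual noise (sd 0.3 — a realistic biological
plus technical spread for plasma NMR on the log scale). Sample ages are
drawn within per-disease ranges matching the printed cohort table, with
cluster-2 samples skewed old (`cluster_corr = 0.6`), reproducing the
age–center–disease triangle. Values below `lod = 8` become non-detects,
making missingness intensity-dependent. QC samples are technical
replicates of the pooled study mean (CV 0.05); HV samples are biological
draws from one designated center's baseline. `default_study_scenario()`
fixes the per-center disease counts and cluster assignment to the study
layout. The same seed yields byte-identical output.

What the generator does **not** emulate: real spectral artifacts (peak
overlap, baseline distortion, alignment error), the full 86-peak
dimensionality (the default namespace has 40 peaks — the signature-table
peaks, the extra confounder-panel peaks and a few pure-noise unknowns),
metabolite-metabolite biological correlations beyond the shared template
shifts, run-order drifts that survive the upstream peak exclusions, and
any true disease biology unless explicitly injected. Passing tests
therefore demonstrate that the *pipeline* behaves correctly under the
declared generative model, not that real plasma NMR data would yield any
particular accuracy.

## Cohort summary conventions

Continuous cohort variables are summarized as mean [range] when a
Shapiro–Wilk test at α = 0.05 keeps normality in both groups, else
median [range], with the matching two-sided t or Wilcoxon test;
categorical variables use a Fisher exact test, switching to a Monte-Carlo
p-value (1e5 tableau draws under a fixed, restorable seed) for tables
larger than 2×2, where exact enumeration is infeasible. Groups under 3
samples report counts only.

## Numerical choices and degenerate inputs

* Component extraction stops early (silently truncating `ncomp`) when the
  deflated X retains no covariance with Y; on the *first* component this
  is an error, except inside CV where it triggers the majority-label
  fallback.
* `ncomp` above `min(n − 1, p)` and PCA ranks above the matrix rank are
  reduced with warnings; k-fold k above the smallest class count is
  reduced with a warning.
* Missing-value token in files defaults to the empty string; a literal
  `"0"` is a measured zero, never a non-detect.
* All simulation, fold assignment and Monte-Carlo code saves and restores
  the caller's RNG state, so library calls never perturb a user's random
  stream; every stochastic routine takes an explicit seed.

## Problem sizes

The test suite and the acceptance script run on deliberately compact
problems — cohorts of 100–400 samples over 12–40 peaks, 2–10 outer
repeats for most property checks, 100 seeds (at 5 outer repeats each) for
the recovery-rate estimates, and oracle sweeps over matrices up to
10×8 — sizes at which every property being asserted is already stable and
a full run stays comfortably interactive.

## Known limitations

* The preprocessing chain is fit on all samples before cross-validation
  (reference spectrum, λ, filters), as is standard practice for unsupervised
  steps; only the model and the optional ASCA correction are refit inside
  folds.
* ASCA handles categorical factors only; a continuous covariate such as
  sample age must be dichotomized (the global median) or handled by
  exclusion instead.
* The robust outlier pass uses plain PCA on robustly centered/scaled data
  with score/orthogonal distance cutoffs, not the sparse-robust PCA
  variants.
* L1-regularized logistic regression is binary only.
* The exclusion approach reduces statistical power by design; its
  signatures are expected to be unstable, which is part of the message
  rather than a defect.
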