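---
title: "Methods: searchlight decoding of tactile stickiness intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: searchlight decoding of tactile stickiness intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickmvpa)
```

## The scientific question

When you touch a sticky surface with a bare fingertip, and when you touch it
through a thin glove, the peripheral events are physically different (skin
stretch at the fingertip versus pressure through the glove), yet both give a
graded percept of stickiness. The analysis implemented here asks two
questions of volumetric fMRI data from such a two-condition experiment:

1. **Within each touch condition**, where in the brain do local multivoxel
   activity patterns discriminate three stickiness intensities?
2. **Across conditions**, is intensity encoded in a *common* spatial code —
   i.e., can a classifier trained on skin-contact trials decode the
   intensity of glove-contact trials, and vice versa?

Because the original scans are not publicly deposited, the package pairs the
full analysis chain with a synthetic-data generator that plants known
multivoxel codes, so every stage is testable end to end and its statistical
operating characteristics (chance level, familywise error, within/cross
dissociation) can be measured on ground truth.

## The experimental design being modeled

The generator reproduces the paradigm's bookkeeping: 2 touch conditions
(skin, glove) × 2 runs × 60 trials, each run holding 15 blocks of the four
stimulus levels 0–3 in randomized order (15 repetitions per level per run),
TR = 1.52 s, trials about 9 s apart, with the decoded event being the moment
the finger *detaches* from the surface. Level 0 is the no-stimulus control;
it is generated, modeled in the GLM, and then excluded from decoding, which
leaves a three-class problem (levels 1–3) with chance accuracy 1/3. With 60
trials per run this yields 120 single-trial regressors per condition.

## Stage 1: single-trial GLM

`canonical_hrf()` builds the standard double-gamma hemodynamic response
(peak gamma shape 6 s, undershoot shape 16 s, peak:undershoot ratio 6,
sampled at 0.1 s on [0, 32] s, peak-normalized). `build_design_matrix()`
places a unit impulse at each Detach onset, convolves with the kernel on the
fine grid, samples at the TR grid, and appends user-supplied nuisance
regressors plus an intercept. `fit_trialwise_glm()` solves ordinary least
squares per in-mask voxel, in one QR decomposition for all voxels; a
rank-deficient design falls back to the minimum-norm (SVD pseudoinverse)
solution with a warning. This is the "least-squares-all" single-trial model:
all 120 trial regressors of a condition sit in one design.

Two modeling choices were genuinely open:

* **Event duration.** Detach is modeled as an impulse (duration 0), since
  the decoded moment is the detachment itself, not the 3-s hold.
* **High-pass filtering.** Instead of filtering the data at 1/128 Hz, the
  drift subspace is spanned by discrete-cosine nuisance regressors with
  periods above 128 s (`cosine_drift_basis()`). Projecting out the cosines
  inside the GLM is equivalent to the filter and keeps a single contract.

`normalize_betas()` z-scores each voxel's trial estimates (center, unit
variance). The normalization *scope* is configurable because run-wise versus
condition-wise standardization is an open choice; the default is `per_run`,
which guarantees that the two-fold run-wise cross-validation never mixes
train and test statistics (no leakage). Zero-variance voxels are set to 0
and counted.

## Stage 2: Gaussian Naive Bayes in a cubical searchlight

The classifier (`gnb_fit()`, `gnb_predict()`) is standard GNB: per class and
feature a sample mean and a maximum-likelihood (biased) variance, priors
from training frequencies, prediction by the maximum of
log prior + Σ Gaussian log-likelihoods. Numerical choices:

* **Variance floor**: per-class variances are clamped at
  `variance_floor` (default 1e-6) × the grand mean of all class/feature
  variances. Z-scored features can have degenerate within-class variance at
  n = 15 per class; the relative floor makes the log-likelihood finite
  without otherwise affecting well-behaved features.
* **Tie-breaking** is deterministic toward the lowest class label, so the
  forced-tie case (identical class distributions) is testable.
* Variances use the ML estimator (divide by n), the common GNB convention;
  at these sample sizes the difference from the unbiased estimator is
  absorbed by the floor.

The searchlight sweeps a 5×5×5-voxel cube over the mask and assigns the
cube-restricted decoding accuracy to the center voxel. Within a condition,
each run is one fold of a two-fold cross-validation; the two fold accuracies
are averaged. Across conditions, the classifier is trained on all level-1–3
trials of one condition and tested on all of the other, in both directions,
and the direction accuracies are averaged; per-direction volumes are kept
for the fold-comparison analysis. Chance (1/3) is subtracted before group
inference.

Implementation note: because the GNB log-likelihood is a sum over features,
the cube sum for *every* center is obtained from whole-volume per-voxel
log-likelihood images via cumulative box sums, making each subject's map an
exact, deterministic computation that costs a few volume passes per test
trial and class instead of one classifier fit per center. Locality is exact:
a center's value depends only on voxels inside its cube.

Edge handling is a design choice the underlying method leaves open: cubes
are truncated at the volume/mask boundary, and centers whose cube holds
fewer than `min_in_mask` (default 30) in-mask voxels are flagged *invalid*
rather than zero-filled, so map edges cannot masquerade as clusters.

## Stage 3: group inference with a sign-flip cluster-size null

`group_ttest()` computes a one-sample t of accuracy-minus-chance across
subjects per voxel (one-sided, positive direction; dof = n−1), only where
every subject's center is valid. Zero-variance voxels get an infinite
sentinel and a flag. `extract_clusters()` thresholds at the Student quantile
for the voxelwise p (default 0.001), labels connected components (6-, 18- or
26-connectivity; default 18, the common volumetric convention), filters by
`size > min_size`, and reports size, peak t, its standard-normal equivalent
(quantile-matching transform), and peak coordinates in voxel and mm units.

The multiple-comparisons correction is the max-statistic permutation scheme:
each subject's whole map is multiplied by ±1 with an independent fair coin,
the group map and its largest suprathreshold cluster size are recomputed,
and 200–1000 such flips give the null distribution of the maximum cluster
size. A cluster is significant when its size reaches the
`threshold_size`, defined as the smallest size whose null upper-tail mass is
at most α (default 0.05, "top 5 % of the upper tail"); each cluster also
gets the add-one empirical p, (1 + #{null ≥ size}) / (1 + n_perm). Two
points deserve emphasis:

* The null cluster-size distribution at these volumes is heavily tied
  (mostly 0, 1, 2), so the threshold is defined through the upper-tail mass
  rather than a plain order statistic; together with the ≥ decision rule
  this guarantees familywise error ≤ α under the symmetric null, which the
  FWER simulation study verifies empirically.
* Sign-flipping assumes the subject-level maps are sign-symmetric around 0
  under the null. One could argue that after chance subtraction accuracies
  lie in [−1/3, +2/3] and positive signs are more probable than negative
  ones; but the *mean* under label-independence is exactly 1/3, deviations
  at realistic searchlight sample sizes are close to symmetric, and the
  exchangeable Bernoulli(½) flip is the standard construction. The chance
  calibration and FWER studies confirm that this assumption holds for the
  data the generator produces.
* The observed labeling is not forced into the null set; at hundreds of
  permutations the difference is negligible and the add-one estimator
  already avoids zero p-values.

Both reporting filters can be applied: the descriptive voxelwise filter
(p < 0.001 with size > 100 at whole-brain scale) and the permutation
threshold; at the small synthetic volumes used in the validation studies the
permutation threshold is the operative one and `min_size = 0` is used.

## Stage 4: confusion matrices and ANOVAs

For a region of interest (typically a significant cross-decoding cluster),
`decode_region()` refits the GNB on the region's voxels and produces one
confusion matrix per transfer direction (rows = true level, columns =
predicted). `compare_directions()` asks whether a region decodes similarly
in both directions: each subject's 3×3 matrix of prediction rates is
z-scored across its own nine cells, and the diagonal (correct-prediction)
z-values of the two directions are compared with a classic two-sample t.
The published description of this test ("two-sample t-tests with z-scored
accuracies") is ambiguous about the standardization unit; z-scoring within
each subject's matrix and comparing diagonals is the interpretation
implemented, recorded in the output metadata, and a diagonal-only default
is used because the off-diagonal cells are linearly constrained by the
diagonal within each row.

`level_accuracy_anova()` runs the one-way ANOVA of per-level
correct-prediction rates (pooling subjects and regions as observations, so
18 subjects × 3 regions × 3 levels would give df = (2, 159)) with Tukey HSD
post hoc via `TukeyHSD()`.

`behavioral_rm_anova()` is the fully within-subject two-factor ANOVA of the
ratings (condition × level), each effect tested against its own
subject-interaction stratum via `aov()`'s `Error()` mechanism; with 18
subjects, 2 conditions and 4 levels the dfs are (1, 17), (3, 51), (3, 51).
The Tukey post hoc on condition differences within each level uses the
studentized range over all 8 condition-by-level cell means with the error
pooled across the three within-subject error strata — the common univariate
approximation for RM designs; the exact error-term convention is not
dictated by the method description and is flagged in the result's `note`.

## The synthetic-data generator

`generate_beta_series()` emulates trial-wise parameter estimates directly:
every trial volume is i.i.d. Gaussian noise (SD `noise_sd`, default 1), and
inside each `planted_region()` the trials of levels 1–3 additionally carry a
level-specific pattern vector drawn once from a standard Gaussian and scaled
by `effect_size` (amplitude in noise-SD units, default 3). `shared` regions
use the same level→pattern mapping in both conditions (decodable within and
across); `condition_specific` regions draw independent mappings per
condition (decodable within only); `null` regions plant nothing. Level-0
trials never carry a pattern, mirroring their exclusion from decoding.
`generate_timeseries()` optionally turns a beta-series ground truth into 4D
BOLD-like data (HRF-convolved sticks + cosine drift + noise) to exercise the
GLM; `generate_ratings()` simulates the per-subject mean ratings.

Deliberate generator design choices:

* **Patterns are drawn per subject** (`subject_specific = TRUE`).
  Fine-grained multivoxel patterns are not expected to align across brains
  after template normalization, so each subject receives an independent
  deterministic draw. This also matters statistically: with a single pattern
  draw shared by all subjects, the condition-specific region's transfer
  accuracy would be one fixed nearest-class-mapping draw (possibly an
  accidental partial permutation of the levels) instead of averaging toward
  chance across subjects and datasets.
* **Trial noise is independent across trials** even though the block
  structure (15 blocks of 4) is recorded — the downstream analysis treats
  trials independently.
* **Rating model defaults** (skin 1.3/2.2/3.6/4.5, glove 1.3/2.2/2.9/3.8 on
  the 1–5 scale; trial SD 0.8, subject SD 0.3) encode the qualitative
  behavioral pattern: levels 0–1 perceived identically in both conditions,
  levels 2–3 about 0.7 points less sticky through the glove, strictly
  increasing in level. Per-subject cell means average 30 trials and are
  clipped to [1, 5].
* All randomness flows through `derive_seed()`, a stable integer hash of
  (master seed, stage, unit), so adding subjects never perturbs existing
  streams and identical seeds give bit-identical outputs.

What the generator does **not** emulate: spatial autocorrelation of noise,
physiological or motion artifacts, inter-subject anatomical variability,
session/registration effects, or any biologically derived pattern form.
Passing the validation studies therefore demonstrates that the *pipeline*
is correct and calibrated for data satisfying its assumptions — not that
real tissue encodes stickiness, and not that the preprocessing steps out of
scope here (motion correction, normalization, smoothing) are handled.

## Validation studies and their sizes

The `study_*()` functions are the package's simulation experiments; the
sizes below are the package defaults.

* `study_chance_calibration()` — 12 subjects, 20³ voxels, no planted
  regions: grand-mean within-condition searchlight accuracy, which must be
  1/3 (three balanced classes, labels independent of data).
* `study_fwer()` — 100 independent null datasets, 8 subjects, 16³ voxels,
  200 flips, voxelwise p < 0.001, α = 0.05: fraction of datasets declaring
  any significant cluster.
* `study_dissociation()` — 20 datasets, 12 subjects, 18³ voxels, one shared
  and one condition-specific 6³ block (216 voxels, the scale of clusters
  reported for this paradigm) in opposite corners separated by a full cube
  width, effect size 3, 100 flips: shared-block detection by cross-decoding
  inference, and the condition-specific block's mean transfer accuracy
  (chance) versus its within-condition accuracy (high). The 6³ block size
  is deliberate: a block wider than the 5³ cube means different centers
  decode from different pattern subsets, so the region-mean transfer
  accuracy averages over many mapping draws.
* `study_rating_anova()` — 100 datasets at n = 18: RM-ANOVA dfs, interaction
  detection, and the level-wise Tukey pattern; 200 datasets under an
  equal-means model for the null rejection rate.
* GLM recovery uses trial amplitudes of SD 2 with timeseries noise 0.8
  (0.4× the amplitude SD). At the paradigm's 9-s trial spacing the
  single-trial estimator error is dominated by the overlap of adjacent
  HRF-convolved regressors, and this noise level places recovery fidelity
  (truth–estimate correlation) comfortably above 0.95.

`scripts/acceptance.R` re-runs the first two studies from scratch and
writes their headline numbers as JSON.

## Known limitations

* The searchlight is cubical only (no spherical or surface variants), and
  GNB is the only classifier, matching the method being modeled.
* GNB uses per-class variances; a pooled-variance variant is noted as an
  alternative formulation but not implemented.
* Cluster tables carry no anatomical labels (no atlas lookup).
* The generator's noise is white; on spatially smooth noise the
  permutation threshold adapts (that is its purpose), but the calibration
  studies here only demonstrate it for white noise.
* `run_full_pipeline()` targets desk-scale synthetic volumes; whole-brain
  real-data runs would want parallelization over subjects.

## A worked example

```{r example, eval = FALSE}
library(stickmvpa)

design <- experiment_design(n_subjects = 6, volume_shape = c(14, 14, 14),
                            seed = 7)
shared <- planted_region(block_region(c(4, 4, 4), c(4, 4, 4)),
                         coding_mode = "shared", effect_size = 3)

maps <- lapply(seq_len(design$n_subjects), function(s) {
  bs <- generate_beta_series(design, list(shared), subject = s)
  bs <- normalize_betas(bs)
  run_searchlight_cross(subset_trials(bs, condition = "skin"),
                        subset_trials(bs, condition = "glove"))
})

stat <- group_ttest(maps)
clusters <- extract_clusters(stat, p_voxel = 0.001)
null <- signflip_null(maps, n_perm = 200, seed = 7)
significant_clusters(clusters, null)
```
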