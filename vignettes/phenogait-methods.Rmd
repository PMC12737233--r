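---
title: "Gait phenotyping and phenotype-specific fall-risk analysis: methods"
author: "phenogait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait phenotyping and phenotype-specific fall-risk analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fall-risk screening in older adults is usually dichotomous: a single indicator
(most commonly the Timed Up and Go test against a 13.50 s cutoff) splits a
heterogeneous population into "at risk" and "not at risk". phenogait
implements an alternative workflow: subjects are first stratified into
*gait phenotypes* — data-driven clusters of statistically similar movement
patterns derived from stride-level inertial signals — and fall mechanisms and
screening cutoffs are then analysed *within* each phenotype. The package
covers the whole chain: stride waveform preprocessing, inter-subject
dissimilarity and clustering with a statistically gated method search,
per-phenotype faller classifiers with consensus feature importance, and
phenotype-specific ROC screening cutoffs. A synthetic cohort generator with
planted phenotypes and fall mechanisms makes every stage testable without
clinical data.

## From raw strides to representative curves

Input recordings are 3-channel foot-dorsum IMU signals — progression
acceleration (`acc_y`, m/s²), vertical acceleration (`acc_z`, m/s²) and
sagittal angular velocity (`gyro_x`, deg/s) — sampled at 104 Hz and
pre-processed with a 4 Hz low-pass filter. We use a 4th-order Butterworth
filter applied forward and backward, so that it is zero-phase: gait events are
not displaced in time, and the DC component is preserved. `signal::filtfilt`
assumes zero initial conditions, so the series is odd-reflection padded
(9 cutoff periods per side) before filtering; without padding the start-up
transient visibly distorts the first ~1 s.

Strides are cut at stride-start events under a half-open
`[start, next_start)` convention (the event source does not state which
window convention was used to average strides; start-to-start is our choice
and is applied consistently). Strides shorter than 2 samples are dropped and
counted. Each stride is linearly resampled onto `L = 100` points of
normalized cycle time — conventional percent-gait-cycle resolution — and a
subject's representative gait is the pointwise mean of its normalized
strides. Strides whose duration falls outside median ± 3 MAD are excluded
from the average by default (configurable off); free-walk recordings contain
turns and stops that produce spurious "strides", and the median ± 3 MAD rule
removes them without tuning.

## Dissimilarity and embedding

The three channels are mixed by one PCA fitted on the pooled
`(subjects × L, 3)` sample matrix; the smallest component count `m` reaching
80 % cumulative explained variance is kept and each subject becomes an
`L × m` series. We read "reduce, then warp" this way — channels reduced
pointwise, time axis preserved — because it is the only reading under which
the reduced object is still a time series on which dynamic time warping is
defined. A t-SNE option is accepted in the configuration for compatibility
but is not available in this build: a t-SNE map of whole subjects is not a
time series, and no t-SNE backend is bundled.

Pairwise dissimilarity is classic unconstrained DTW (steps match / insert /
delete, local cost = Euclidean distance across the `m` channels), computed in
C++ for the full subject-pair matrix. Two matrix modes exist: waveform-only,
and waveform fused with anthropometry, where a Euclidean distance on
cohort-standardized age and height is added after max–min rescaling both
blocks to `[0, 1]`:

`D = rescale(D_wave) + lambda * rescale(D_basic)`, `lambda = 1` by default.

Whether basic data should enter the warping cost itself or a separate
distance block is genuinely open; we chose the additive block because it
keeps the warping purely kinematic and makes the fusion weight explicit.
`lambda = 1` gives the blocks equal weight after rescaling; raising `lambda`
can only increase off-diagonal dissimilarities (a tested invariant).

The matrix is embedded by metric least-squares multidimensional scaling via
iterative stress majorization (the SMACOF update), initialized from the
classical-scaling solution plus a tiny seeded perturbation, iterated until
the relative raw-stress decrease falls below 1e-10 (cap 500 iterations);
Kruskal stress-1 is reported. The embedding dimension defaults to `d = 5`:
large enough to hold four clusters with curvature to spare, small enough
that Davies–Bouldin distances remain meaningful. An all-zero dissimilarity
matrix embeds to coincident points by definition rather than iteration.

## The gated method search

Candidate conditions are the cross of clustering algorithm (k-means++,
k-medoids++, fuzzy c-means, average-linkage hierarchical), cluster count
`k ∈ {3, 4, 5}` and matrix mode. k-means++ and fuzzy c-means run on the
embedding with careful D²-sampling seeding (10 seeded restarts, best
objective kept, collapsed solutions re-seeded); k-medoids runs directly on
the dissimilarity matrix (D²-seeding, then PAM swap refinement);
hierarchical clustering is deterministic on the matrix. The fuzzy exponent
is 2.0 with defuzzification by maximum membership. Average linkage is our
choice where the linkage is unstated — it is the least shape-biased of the
common linkages on non-Euclidean dissimilarities.

Each condition must first pass an effect-size gate on seven key fall-related
parameters (cadence, step speed, stride length, clearance, swing share,
SPPB, TUG): per parameter, Shapiro–Wilk (alpha 0.05) in every cluster decides
between one-way ANOVA with eta² = SS_between/SS_total and Kruskal–Wallis
with epsilon² = H·(N+1)/(N²−1) (= H/(N−1)); the condition passes if the
effect size *strictly* exceeds 0.14 — the minimum clinically meaningful
effect — for at least 4 of the 7 parameters. Clusters with fewer than 3
members, or with zero spread, force the rank branch (normality is untestable
there).

Gate-passing conditions are ranked by a composite of internal indices:
silhouette (from the dissimilarity matrix), Davies–Bouldin (from the
embedding) and cluster balance (largest minus smallest cluster size). Each
index is max–min normalized across the passing set, directions aligned, and
summed with equal weights — equal because nothing justifies any other
weighting. Degenerate indices (constant across the passing set) contribute
0.5, a neutral value that keeps the composite defined when only one
condition passes (its composite is then 1.5). Ties break on raw silhouette.

## Per-phenotype faller models

Within each phenotype, four classifier families distinguish fallers (≥ 1
fall in 12 months) from non-fallers on 25 features: the stride-derived gait
parameters (means and stride-to-stride SDs), free-walk totals, and clinical
scores (GDS, Fried frailty, Short FES-I, SPPB, 4 m gait speed, TUG). TUG is
deliberately retained as a feature. Age and height are excluded — they enter
only the dissimilarity fusion.

Preprocessing is family-specific and fitted on training folds only: mean
imputation + z-scoring for the tree families; median imputation, IQR
clipping to `[Q1 − 1.5 IQR, Q3 + 1.5 IQR]` and robust (median/IQR) scaling
for the neural net. Hyperparameters are tuned by exhaustive grid search
under stratified 5-fold cross-validation with inverse-frequency class
weights and mean validation F1 as the criterion; the winner is refit on all
data (the neural net with a doubled iteration cap, since the refit should
not be stopped by the tuning-time budget). Metrics (accuracy, precision,
recall, specificity, F1) are summarized per fold as mean ±
1.96·SD/√5 — a normal-approximation 95 % CI, the simplest interval
consistent with "mean (95 % CI) of k-fold CV". Undefined ratios (zero
denominators) are reported missing, never coerced to zero, and fold
averaging skips them.

Backends are the standard R implementations, and each family's search grid
is expressed in its backend's parameter space: `randomForest` (trees
100–300, feature-subset strategy sqrt/log2/all, leaf size 1–4), `xgboost`
(rounds 100–300, depth 3–9, learning rate 0.01–0.2, row and column
subsampling 0.8–1.0, logistic objective), `rpart` (Gini/information,
depth 5–30, split/leaf minima) and `nnet` (single-hidden-layer size 50–150,
L2 decay 1e-4–1e-2, iteration cap 500–1500). Two mappings deserve note:
`rpart` exposes no random-splitter or per-split feature subsampling, and
`nnet` is a single-hidden-layer BFGS network without Adam-style early
stopping, so multi-layer topologies and patience-based stopping are not
part of the searched space. The end-to-end pipeline and the shipped
analysis scripts use documented compact sub-grids (4–8 settings per family):
with a few dozen subjects per phenotype most of the full grid is flat in
validation F1, and the compact grids keep a full cohort run in minutes on
one core.

## Attributions and weighted Borda consensus

Global feature importance per model is the mean absolute per-subject
attribution toward the fall class. The attribution methods keep the additive
local-accuracy contract — base value plus the row's attributions equals the
model's positive-class output:

* gradient boosting: the backend's exact TreeSHAP decomposition (log-odds
  scale);
* random forest and decision tree: an exact interventional tree-Shapley.
  For a fixed foreground/background pair, a leaf is reached under coalition
  `S` iff `A ⊆ S` and `B ∩ S = ∅`, where `A` holds the features whose leaf
  conditions only the foreground passes and `B` those only the background
  passes; such a unanimity-style game has closed-form Shapley values
  (`(|A|−1)!|B|!/(|A|+|B|)!` per member of `A`, mirrored for `B`), so the
  attribution is an exact sum over leaves averaged over a fixed 25-row
  background subset (probability scale);
* neural net: permutation-sampling Shapley values (32 permutations, same
  background, fixed seed); each permutation telescopes, so local accuracy is
  exact even at small sample counts, and only the per-feature allocation is
  stochastic.

Per model, features get descending ranks with average ties (half-integer
ranks arise naturally when a model — typically the single decision tree —
assigns many features zero importance). The consensus score of feature `i`
is the weighted Borda sum `S_i = Σ_j w_j (n − r_ij + 1)` with `n = 25` and
`w_j` the model's raw (unnormalized) mean CV accuracy; raw accuracies are
the only weighting under which the published worked examples reproduce, and
the conventional "strong consensus" reading (`S_i > 60`) is flagged at
`n = 25`. Ties in `S_i` break by the random-forest rank. A three-model
(trees-only) consensus is available as a configuration option.

## TUG screening cutoffs

Within each phenotype, candidate cutoffs are the midpoints between
consecutive distinct sorted TUG values plus below-minimum and above-maximum
sentinels; prediction is "faller iff TUG ≥ cutoff", and the cutoff
maximizing the Youden index J = sensitivity + specificity − 1 is chosen.
Midpoint candidates are what make non-observed cutoff values possible; ties
in J break toward higher sensitivity, because in screening a missed faller
costs more than a false alarm, then toward the lower cutoff. The comparison
against the fixed 13.50 s standard is computed in-sample (no
cross-validation), matching how such exploratory reference values are
usually reported — they are labelled exploratory, not clinical cutoffs.

## The synthetic cohort generator

The generator is the package's test bed, and its defaults are the study
conditions the rest of the package assumes. Four archetypes span the
functional spectrum: *high-cadence* (fast-stepping compensators, cadence
53.7 strides/min), *cautious* (frail, slow, cadence 46.5, highest fall
prevalence), *intermediate* (propulsion deficit), and *robust* (fast,
long-striding, lowest prevalence). Gait and clinical means (cadence, step
speed, stride length, SPPB, TUG, Short FES-I and their SDs) follow the
ranges published for foot-worn-IMU cohorts of community-dwelling older
adults; parameters not published at the phenotype level — gait-phase
fractions, clearance, foot angles, demographics — were fixed once from
normative gait values (load ≈ 9–14 %, foot-flat ≈ 40–48 %, push ≈ 11–17 %,
swing ≈ 26–34 %; clearance 0.12–0.19 m). Per subject, latent gait
parameters are drawn from the archetype's means and SDs; stride counts are
uniform on 20–60 (free-walk lengths vary and are otherwise unpublished);
5 % of clinical fields can be masked to exercise the imputation paths.

Stride waveforms are event-locked Gaussian bumps plus white noise, not a
biomechanical simulation — the pipeline only needs class-discriminative
morphology. Three physical couplings matter, because time normalization
would otherwise erase cadence entirely: accelerations scale with the squared
cycle frequency (harmonic motion), angular rate with cycle frequency, and
the heel-strike transient (impact bump plus damped 7 Hz ringing) has a fixed
real-time width, so its percent-cycle footprint shrinks as cadence rises.
Per-stride duration jitter (CV 4.5–9 % by archetype) makes stride lengths
differ, and the subject's gait parameter table is derived from the realized
strides, keeping features and waveforms consistent.

Fall labels are planted per archetype: fall probability is
`plogis(intercept + beta * z)` with `z` the archetype's driver feature
standardized within the group — Short FES-I (+2.0) for high-cadence and
robust, 4 m gait speed (−2.5) for cautious, push-phase share (−2.0) for
intermediate — and the intercept calibrated by root finding so the expected
prevalence matches the archetype's target (0.56, 0.68, 0.48, 0.27). Slopes
of ~2 per SD are "strong but not deterministic" mechanisms: they leave
substantial label noise, which is what makes consensus-importance recovery a
meaningful test.

A scalar *separation* dial moves every archetype mean along
`grand_mean + separation · (mean − grand_mean)`: 0 collapses the archetypes
(downstream recovery must be at chance), 1 is the study-like default with
heavily overlapping phenotypes, and values ≥ ~6 give a clearly separable
regime in which the method search reliably selects `k = 4` and recovers the
planted phenotypes (adjusted Rand index ≥ 0.8). The dial scales only
between-archetype contrast; within-phenotype SDs stay fixed, which is why
the study-like default is genuinely hard — exactly as the real cohort's
overlapping phenotype profiles suggest it should be.

What the generator does *not* emulate: sensor orientation drift, gravity
leakage, turning and non-steady gait, event-detection errors,
non-Gaussian clinical score distributions, and correlations between
clinical scores beyond those induced by the shared archetype. Passing tests
therefore show that the pipeline recovers structure of the planted kind,
not that it would behave identically on any real cohort.

## Problem sizes and numerical choices

The shipped tests and analysis scripts run the full cohort at `n = 146`
subjects, `L = 100`, `d = 5`, 24 clustering conditions; calibration checks
use `n = 2000–4000` with 5–8 strides per subject (prevalence does not depend
on stride count); driver-recovery runs use 3 seeds × 4 phenotypes with the
compact grids. DTW is exact (no window); SMACOF stops at relative stress
change 1e-10; fuzzy c-means at 300 iterations; effect sizes are clamped to
`[0, 1]`; max–min rescaling of a constant block yields zeros (dissimilarity)
or 0.5 (composite indices); k-means/fuzzy restarts that collapse a cluster
are re-seeded up to 20 times. All stochastic stages derive child seeds
deterministically from one master seed; two runs with the same configuration
are byte-identical.

## Known limitations

* The neural-net family is a single-hidden-layer BFGS network; architectures
  and optimizers beyond `nnet`'s scope are not searched.
* Boosted-tree attributions are on the margin (log-odds) scale while the
  other families are on the probability scale; rank-based consensus makes
  the scales commensurable, but raw attribution magnitudes are not
  comparable across families.
* Screening cutoffs are in-sample and uncorrected for optimism; they are
  exploratory reference values.
* Faller contrasts are reported at per-variable alpha = 0.05 without
  multiplicity correction (an FDR switch exists), mirroring the reporting
  convention of phenotype-profile tables.
* The t-SNE reducer option is declared but unavailable; clustering quality
  under it is untested by construction.
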