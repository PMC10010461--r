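---
title: "Factorized decoding of motor sequence order and timing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorized decoding of motor sequence order and timing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqfact)
```

## The scientific problem

Trained finger-press sequences have two separable high-level features: the
*order* of the effectors and the *timing* of the presses (the four
interpress intervals, IPIs, of a five-press sequence). A 2 x 2 design that
crosses two orders with two timing structures makes it possible to ask, for
any brain region, three distinct questions about its activity patterns:

1. Does it carry order information that *generalizes* across the timing it
   is paired with?
2. Does it carry timing information that generalizes across order?
3. Does it carry *integrated* sequence information — pattern structure
   unique to a specific order-timing conjunction that no additive
   combination of the two feature patterns can explain?

`seqfact` implements the full analysis chain for these questions —
condition-by-run beta estimation, factorized classification, searchlight
and ROI aggregation, and group inference — together with behavioral scoring
of the underlying task and a synthetic-data generator with known ground
truth that makes every stage testable.

## The generative model behind the synthetic data

`simulate_patterns()` draws one beta pattern per condition-by-run cell
(2 orders x 2 timings x 6 runs by default) as

> beta(o, t, r) = m + a_o P_o + a_t Q_t + a_i R_ot + u_r + noise,

where `P`, `Q` are one fixed random voxel pattern per order and timing
level, `R_ot` is the interaction component, `u_r` an additive per-run
pattern shared by all conditions, and the noise i.i.d. Gaussian (an AR(1)
voxel correlation can be switched on). All structural components are drawn
once per dataset and reused in every run, so genuine signal generalizes
across runs while run effects and noise do not.

The interaction component is built by drawing one random pattern per
condition and *double-centering* it across the 2 x 2 grid: within every
run, its mean across orders at fixed timing and across timings at fixed
order is exactly zero. Two consequences matter:

* With `integ_amp = 0` the condition means are exactly additive, so the
  integrated classifier's null hypothesis is true by construction — this is
  the testable null used to validate specificity.
* In a 2 x 2 design, any zero-marginal component is necessarily
  anti-symmetric: `R_11 = -R_12 = -R_21 = R_22`. Double-centering a grid of
  i.i.d. patterns also halves their per-voxel SD, so the effective
  interaction amplitude is `integ_amp / 2`.

The second point has a substantive corollary for cross-classification. When
a strong interaction is present but a feature's own amplitude is zero, the
class difference the order classifier learns at one timing is the *sign
flip* of the difference it meets at the other timing. Feature transfer is
then driven *below* chance, not merely to chance. This is a property of
factorized 2 x 2 designs themselves, not of this implementation: transfer
decoding is a one-sided instrument. It cannot produce spuriously
above-chance feature decoding from interaction signal (the direction that
matters for the scientific claims), but below-chance transfer is the
signature of integrated coding interfering with feature generalization.
The test suite checks exactly these attainable properties: transfer at
chance under a strong non-decoded additive feature, never above chance
under a strong interaction, and above chance only when the decoded
feature's amplitude is positive.

Defaults were chosen once as a realistic desk-scale regime: unit feature
amplitudes against `noise_sd = 0.5` and `run_sd = 0.5` at 160 voxels give
single-dataset feature decoding around 70-100% accuracy, comparable to a
well-decodable region; the paper gives no empirical amplitude estimates, so
these are free parameters of the simulation, swept in tests rather than
fitted. What the generator does *not* emulate: spatially structured
signal topographies, physiological noise spectra, or inter-subject
variability in signal location — passing tests validate the algorithms,
not claims about any particular real dataset.

## Behavioral task machinery

The four target sequences share their first finger (so first-press identity
cannot drive preparation-phase decoding) and cross two finger orders with
two fixed timing structures, Timing 1 = 1200-810-350-650 ms and
Timing 2 = 350-1200-650-810 ms, matched in total duration (3010 ms).

* **Press detection** (`detect_presses()`): each 1000-Hz force channel is
  baseline-corrected by the mean of the 500 ms before the Sequence cue,
  smoothed with a Gaussian window (interpreted as FWHM = 100 ms, a common
  smoothing convention; exposed as a parameter), and thresholded (default
  1 N, the apparatus value used for most participants; 2.5 N for an early
  subset). One onset is emitted per threshold-crossing episode; a new press
  on the same channel requires the force to drop below threshold first —
  the episode rule is our choice, since the apparatus description does not
  state one.
* **Timing error** (`timing_error()`): produced and target IPIs are
  normalized as percentages of the participant's average total sequence
  length, and the absolute percent deviations are summed over the four
  intervals. The normalization deliberately removes global tempo: producing
  everything 10% slower than target scores zero error if the participant's
  average length scales with it.
* **Scoring** (`score_trial()`): up to 5 points for initiation RT and 5 for
  timing (mean absolute IPI deviation in percent of the respective target
  interval), with the band edges closed on the left and open on the right
  (the prose bands overlap at their boundaries; a convention had to be
  fixed). Wrong order or a preparation-period force crossing voids the
  trial; No-Go trials score 5 when silent, 0 otherwise.
* **Transfer statistics** (`transfer_stats()`): synchronization deviations
  are averaged from the fourth exposure of each sequence onward (earlier
  exposures reflect initial adjustment rather than transfer) and each
  condition is compared against new sequences with a paired t test,
  one-sided toward a benefit by default. Zero-variance difference vectors
  are flagged as degenerate rather than propagating NaN.

## First-level GLM

Planning and execution are separated by regressor design rather than by
trial phase estimates: per condition, preparation is modeled *only from
No-Go trials* (a 2500 ms boxcar from the Sequence cue — the maximum
preparation phase), and production *only from Go trials* as a constant
impulse at the first press (sequence initiation, not duration, drives the
BOLD response of interest). Error trials (cue to end of ITI) and the Go-
trial preparation window (1000-2500 ms post-cue) are nuisance regressors,
every regressor gains a temporal derivative, and all are convolved with the
canonical double-gamma HRF (delays 6/16 s, dispersions 1/1, ratio 6, 32 s
support — the conventional parameter set, since only "the standard HRF" is
specified) at microtime resolution TR/16 before sampling at the scan grid.

Estimation is ordinary least squares; no autocorrelation modeling is
applied because the synthetic noise is white by default. The robust
weighted-least-squares variant used on real scanner data is deliberately
out of scope. Rank-deficient designs raise an error naming the collinear
columns. One practical caveat the tests make explicit: constant-impulse
regressors have little energy, so their beta standard errors are several
times the noise SD — jittered trial onsets (as in the actual paradigm)
keep the design well-conditioned.

## The decoding core

* **Folds** (`build_folds()`): feature schemes train on the two levels of
  the decoded factor paired with *one* level of the other factor across
  all-but-one runs, and test on the held-out run with the *other* pairing;
  both pairing directions for each of 6 held-out runs give 12 folds. The
  integrated scheme is a plain leave-one-run-out over all four conditions
  (6 folds).
* **Classifier** (`lda_fit()`): Gaussian LDA with class means and a single
  pooled covariance, shrunk as `(1 - λ) S + λ (tr(S)/p) I` with λ = 0.1 by
  default. Shrinkage is not optional in practice: 160 voxels against
  10-20 training patterns leaves `S` rank-deficient. Ties break toward the
  lowest class index for determinism. A brute-force evaluation of the full
  Gaussian densities serves as an independent oracle in the tests.
* **Residualization** (`residualize_integration()`): within each run the
  run mean and both marginal mean patterns are subtracted (double-centering
  over the 2 x 2 grid), leaving only non-additive structure; the operation
  is idempotent and its output has zero marginals to machine precision.
* **z transform** (`accuracy_to_z()`): accuracies are pooled across folds
  (correct/total) and standardized against the binomial null,
  `z = (acc - chance) / sqrt(chance (1 - chance) / n)`, with chance 0.5 for
  the pairwise feature schemes and 0.25 for the 4-way integrated scheme.
  Pooling before the transform (rather than z-transforming per fold and
  averaging) was chosen because the folds' test sets are small (2-4
  patterns) and pooled counts have the stated binomial distribution.
* **Searchlight** (`searchlight()` + `make_neighborhood_graph()`): each
  node's neighborhood is its 160 nearest voxels within a 6 mm radius cap
  (cap applied before the size cap), built on a synthetic 3-D grid or 2-D
  sheet standing in for the cortical surface — surface reconstruction is
  irrelevant to algorithm correctness. The z of each neighborhood is
  assigned to its center.

## Group inference

`one_sample_tests()` runs per-ROI t tests against chance (zero) with
Bonferroni correction for a declared family (default 6 = 3 classifiers x 2
phases). Zero-variance inputs are flagged: exactly-at-null constants report
t = 0, p = 1; off-null constants report NA rather than NaN.

`permutation_cluster_1d()` implements one-sided sign-flip permutation
cluster inference for subjects x positions profiles: positions exceeding a
cluster-forming threshold (one-sample t at uncorrected p < 0.05 — the
threshold is not printed anywhere authoritative, so it is exposed as an
option) form contiguous clusters summarized by mass (sum of t; size is the
alternative), and the observed cluster statistics are referred to the
permutation distribution of the *maximal* cluster statistic under random
per-subject sign flips (10,000 permutations by default), giving family-wise
corrected p values `(1 + #{null >= obs}) / (n_perm + 1)`. Cohen's d per
cluster defaults to mean/SD of the cluster-averaged per-subject values
(averaging values before computing d); the per-position alternative is
implemented and selectable, since the verbal description is ambiguous
between the two. The RNG seed is a required argument. With a one-sided
test and all-negative group means, no clusters are returned by
construction.

Calibration is checked in the test suite by simulation: over 500 null
profile replicates (16 subjects x 40 positions, 1000 permutations each) the
family-wise false-positive rate must fall inside the central 95% binomial
interval around 0.05.

## Problem sizes used in the tests

The suite validates properties at desk scale, chosen once: Monte-Carlo
nulls use 100-200 replicate datasets at 160 voxels; LDA-versus-oracle
checks use 4-class, 10-voxel problems; the end-to-end pipeline simulates 6
subjects x 6 runs x 100 scans at 40 voxels, plants additive or interaction
structure, and requires feature decoding (and integration decoding only
when planted) to reach group significance. The permutation calibration
uses 1000 permutations per replicate rather than 10,000, which bounds the
resolvable p at 0.001 — ample for a 0.05-level calibration check.

## A worked pipeline

```{r pipeline, eval = FALSE}
ds <- simulate_patterns(sim_config(n_voxels = 160, order_amp = 1,
                                   timing_amp = 1, integ_amp = 0,
                                   noise_sd = 0.5, seed = 1))
decode(ds, "order")       # transferable order information
decode(ds, "timing")      # transferable timing information
decode(ds, "integrated")  # conjunction information (null here)
```

## Known limitations

* Only the 2 x 2 order-by-timing design is supported by the fold
  constructor; the generator accepts larger factors but the transfer
  machinery does not.
* The searchlight lattice is a geometric stand-in; no cortical geometry,
  inter-subject anatomy, or surface projection is modeled.
* No prewhitening / AR modeling in the GLM, and no robust WLS.
* Repeated-measures ANOVA with sphericity corrections is standard
  statistics and intentionally left to general-purpose tools.
* Whole-cortex cluster tables from real scans are not reproducible without
  the original data; group-level machinery is validated on synthetic
  profiles instead.
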