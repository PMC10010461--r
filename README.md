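# seqfact

Factorized decoding of motor sequence **order** and **timing** from fMRI
activity patterns, and of their nonlinear **integration** — plus the
behavioral machinery of the underlying delayed sequence-production task.

## The problem

Trained five-finger sequences combine two separable features: which finger
presses when (order) and the temporal structure of the four interpress
intervals (timing). In a 2 × 2 design crossing two orders with two timing
structures, three classifiers ask three different questions of a region's
condition-by-run beta patterns:

- **Order classifier** — trained to separate the two orders paired with one
  timing (across all-but-one runs), tested on the held-out run with the
  *other* timing pairing; both directions for each held-out run give
  **12 cross-validation folds**. Only order information that generalizes
  across timing can support accuracy.
- **Timing classifier** — the mirror image, transferring across order.
- **Integrated classifier** — 4-way leave-one-run-out classification
  (**6 folds**) of *residual* patterns: within each run, the run mean and
  both marginal feature patterns are subtracted, so only conjunction
  information not explained by any linear combination of order and timing
  remains.

The classifier is Gaussian LDA with class means and a pooled covariance
shrunk toward a scaled identity, `(1 − λ)S + λ(tr S/p)I` (λ = 0.1; with 160
voxels and 10–20 training patterns, regularization is mandatory). Pooled
accuracies are standardized against the binomial null,

```
z = (acc − chance) / sqrt(chance · (1 − chance) / n_tests)
```

with chance 0.5 (feature schemes) or 0.25 (integrated), assigned to
searchlight centers (160 voxels within a 6 mm radius cap), averaged within
ROIs, and taken to group level by one-sample t tests (Bonferroni-corrected)
or one-sided sign-flip permutation cluster tests along 1-D cortical
cross-section profiles (10,000 permutations, max-cluster null).

The behavioral side covers press detection from 1000-Hz force traces
(500 ms baseline correction, 100 ms Gaussian smoothing, 1 N threshold with
episode logic), IPI extraction, tempo-normalized timing error, the 0–10
points feedback scheme, trial schedules for every experimental phase
(3 × 240 training trials, 288-trial scanner session at 50/50 Go/No-Go), and
synchronization-transfer statistics. A first-level GLM module builds the
preparation (2500 ms No-Go boxcar) and production (constant impulse at
first press) regressor scheme with HRF convolution, and a synthetic-data
module generates voxel patterns, BOLD runs, force traces and trials with
known ground truth so the whole chain is testable without scanner data.

## Worked example

```r
library(seqfact)

# patterns with additive order + timing signal, no interaction
ds <- simulate_patterns(sim_config(n_voxels = 160, order_amp = 1,
                                   timing_amp = 1, integ_amp = 0,
                                   noise_sd = 0.5, seed = 1))
ds
#> pattern_dataset: 2 orders x 2 timings x 6 runs, 160 voxels

decode(ds, "order")
#> decoding_result (order): accuracy 1.000 (chance 0.500, n = 24), z = 4.899
decode(ds, "timing")
#> decoding_result (timing): accuracy 1.000 (chance 0.500, n = 24), z = 4.899
decode(ds, "integrated")
#> decoding_result (integrated): accuracy 0.292 (chance 0.250, n = 24), z = 0.471
```

Both features decode perfectly (24/24 test classifications, z = 4.9), while
the integrated classifier sits at its 4-way chance level of 0.25 — there is
no conjunction signal to find. Planting one (`integ_amp = 1`, `noise_sd = 1`)
flips that conclusion:

```r
ds2 <- simulate_patterns(sim_config(n_voxels = 160, order_amp = 1,
                                    timing_amp = 1, integ_amp = 1,
                                    noise_sd = 1, seed = 1))
decode(ds2, "integrated")
#> decoding_result (integrated): accuracy 0.583 (chance 0.250, n = 24), z = 3.771
```

Behavioral scoring works the same way on single trials: a sequence begun
150 ms after the Go cue whose intervals all run 5% long earns the full
5 + 5 points, and a 100 ms overshoot on the first 1200 ms interval of
Timing 1 costs 3.32% cumulative timing error after tempo normalization:

```r
timing_error(c(1300, 810, 350, 650), c(1200, 810, 350, 650), 3010)
#> timing error: per interval 3.32%, 0.00%, 0.00%, 0.00% | cumulative 3.32%
```

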