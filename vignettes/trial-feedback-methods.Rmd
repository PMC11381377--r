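---
title: "Trial-feedback motor-imagery training: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-feedback motor-imagery training: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitrainr)
```

## The problem

Two-class motor-imagery (MI) brain-computer interfaces ask a subject to
imagine left- or right-hand movement while EEG is recorded over the
sensorimotor cortex. Imagining a hand movement attenuates the ~10 Hz mu
rhythm over the *contralateral* hemisphere (event-related
desynchronization, ERD) and typically enhances it ipsilaterally (ERS).
Decoding this lateralization is routine; getting *subjects* to produce
it reliably is not — a sizeable fraction never reach the conventional
70% accuracy benchmark. `mitrainr` implements a training protocol that
attacks the human side of the loop: after every calibration trial the
subject is shown a topography of their ERD/ERS pattern with a
qualitative "good"/"fight" verdict, after every calibration run a
quantitative feature-separability score, and at any time they can veto a
distracted trial by blinking. Around this sit the standard decoding
stages: band-pass filtering, epoching, variance-based artifact
rejection, Riemannian alignment, CSP spatial filtering and LDA.

All stages are exercised end to end on a synthetic session generator, so
the package is fully testable without recorded data.

## Session structure and timing

A session is one EOG run (20 two-second blink/no-blink trials), six
calibration runs of 20 trials (10 per class), and four testing runs of
10 trials (5 per class). Decoders are trained twice — on the first three
runs and on all six — and applied to the first two and last two testing
runs respectively. Each MI trial has 2 s of (unrecorded) preparation,
4 s of imagery recorded at 256 Hz from 21 electrodes (the FC/C/CP rows,
positions 5/3/1/z/2/4/6), and a 2 s confirmation window in which only
the prefrontal EOG channel (Fp2) matters. Time is measured in seconds
from cue onset with half-open sample windows, so the training epoch
(0.5, 2.5) s is exactly 512 samples and the three feedback segments
(0.5, 1.5), (0.5, 2.5), (0.5, 3.5) s are 256/512/768 samples.

## Per-trial feedback

The 4-s window is re-referenced (common average over the 21 electrodes
by default), band-passed to the rhythm band, and converted to an
envelope via the analytic-signal magnitude; the per-channel mean
envelope over the window is subtracted as baseline. Averaging the
deviations over each feedback segment gives three 21-channel
topographies `R[k, j]`.

For a left-hand trial, a left-hemisphere electrode is "correctly
activated" when its deviation is positive (ERS) and a right-hemisphere
one when negative (ERD); for right-hand trials the sides swap. The
representative segment is the one with the most correctly activated
electrodes, with a priority rule: segments correct on *both* hemispheres
permanently outrank segments correct only on the expected-ERS side, ties
keep the earliest segment, and if nothing is correct the middle segment
is shown. The selected map is scored under both class hypotheses: each
hemisphere sums, over electrodes of the hypothesis-consistent sign, the
ratio of the deviation to the hemisphere's extremum of that sign. Each
ratio lies in (0, 1], so a score lies in [0, 18]; midline electrodes
never contribute. The verdict is "good" exactly when the true class's
score attains the maximum (ties included).

Three choices here were genuinely open and are fixed as follows:

* **Reference.** "Local average" is implemented as the common average of
  the 21 sensorimotor electrodes (they are already a local subset of a
  full cap); a nearest-neighbour surface Laplacian over the 3×7 grid is
  available via `reference_mode = "laplacian"`.
* **Envelope band.** 8–30 Hz (mu + beta). Using the full 0.1–30 Hz
  signal would let slow drifts dominate the envelope and swamp the
  rhythm-amplitude effect the score is meant to capture.
* **Baseline.** The mean envelope over the 4-s window itself, because no
  pre-cue data is recorded. This guarantees both signs occur across the
  window, which the electrode-counting rule needs to be meaningful.
* **Selection metric reset.** The per-segment metric is reset to zero at
  each segment; carrying a stale value into segments matching neither
  branch would contradict the best-map intent of the rule.
* **Extremum denominators** are taken over the sign-restricted subset
  only; an unrestricted extremum could produce ratios outside [0, 1].

### A known bias of the verdict

The segment-selection step looks at the *true* label, so under a null
effect it picks whichever of three noisy maps happens to agree best with
the true class — inflating that class's score. The measured consequence
(reported by `scripts/acceptance.R` as `good_verdict_rate_null`) is a
"good" rate of about 0.68 at zero effect, versus 0.48 when the segment
is held fixed. Practitioners should therefore read the "good" rate as a
*relative* signal across runs and subjects, not as an absolute
probability of genuine ERD/ERS; a subject producing nothing will still
hear "good" two times in three.

## Blink gating

The EOG run's blinking trials yield peak-amplitude features; features
strictly above twice their median or strictly below half of it are
pruned, and the threshold is the mean of the survivors (boundary
features survive; the median of an even-length set is the usual midpoint
convention). A calibration trial is discarded when its confirmation-phase
EOG peak strictly exceeds the threshold. "Peak" is maximum *absolute*
amplitude: blinks are biphasic and electrode polarity is
montage-dependent. Only blinking-labeled EOG trials feed the
calibration; labels of gated trials are never altered.

## Filtering

Trials are band-pass filtered 0.1–30 Hz with an 8-pole Butterworth and
band-stop filtered 48–52 Hz (power-line) of the same order, designed via
`signal::butter` and factored into second-order sections — with a 0.1 Hz
edge the expanded transfer-function form is numerically fragile.

Zero-phase application needs care on 4-s trials: the 0.1 Hz pole has a
multi-second impulse response, so a recursive forward–backward pass
never escapes its own start-up transient inside the window. The default
offline mode therefore multiplies the DFT of the trial's even periodic
extension by |H(ω)|² — the exact limit of forward–backward filtering,
with no transient and no group delay (measured on 4-s trials: 10 Hz
passed at 0.999, 50 Hz at −42 dB before the notch, a 100 µV DC offset
reduced to ~10⁻⁶ µV). A `causal` mode runs the sections forward only
with steady-state initialisation, for faithful real-time simulation;
which mode the original online system used is unknowable from the
protocol description, so both are provided and recorded in output
manifests.

## Artifact rejection

After gating and epoching, per-channel variances are computed per trial
(unbiased estimator). Channels where more than 10% of trials fall below
0.5 µV² are excluded from thresholding (computed once, before the loop).
Then, iteratively: pool the retained-channel variances, set
`threshold = P90 + 3·(P90 − P10)` (percentiles by R's default
linear-interpolation convention, which the package records because the
worked behaviour depends on it), remove every trial whose *maximum*
retained-channel variance strictly exceeds it, and stop when an
iteration removes nothing. A single saturated channel dooms a trial by
design. Screened channels are excluded only from thresholding; all 21
channels proceed to decoding.

## Decoding

Per-trial covariances are mean-removed, (N−1)-normalized, and ridged by
10⁻⁸ of the mean diagonal. Each calibration run is re-centred by
right-multiplying its trials with the inverse square root of the run's
Karcher mean (the SPD mean under the affine-invariant metric, computed
by the standard fixed-point iteration from the arithmetic-mean start,
tolerance 10⁻⁹ on the tangent-space gradient, 50-iteration cap with a
warning on non-convergence). Alignment uses no labels.

CSP solves `P1 w = λ P2 w` for the class-average aligned covariances,
rows sorted by descending λ; the spatial filters are the first and last
three rows. Scale is fixed by `wᵀ(P1+P2)w = 1` and sign by making the
largest-magnitude coefficient positive, so exported filter topographies
are reproducible across refits. Features are log-variances of the six
projections; LDA uses the unweighted average of the two class
covariance matrices, with decision value exactly 0 mapping to class 1
(a tie rule the sign convention leaves open). Testing trials are
filtered, epoched at (0.5, 2.5) s, aligned by the single Karcher mean of
*all* training trials' raw covariances (not a mean of per-run means),
projected and classified. Covariances are not trace-normalized before
alignment (a config switch exists); nothing in the protocol description
settles this, and the end-to-end behaviour is insensitive to it in the
generator's regime.

## Run evaluation and statistics

After each calibration run, within- and between-class scatter matrices
of the six-dimensional features give the class distance
`CD = ‖Sb‖/‖Sw‖`. The matrix norm is a convention; the default is the
entrywise sum of absolute values, with induced-1-norm and trace options.
CD is exactly invariant to global feature scaling under all three; only
the trace norm is rotation-invariant, a sensitivity users comparing CD
across studies should note. The 2-D projection shown to subjects is the
(first, last) feature pair.

Offline accuracy uses stratified 10×10-fold cross-validation: alignment
is applied per run beforehand (label-free, so nothing leaks), CSP and
LDA are refit inside every fold. Whether the original analysis refit CSP
per fold is unstated; the leakage-safe protocol is the defensible
default. Paired t-tests and Pearson correlations wrap `stats::t.test`
and `stats::cor.test`. `reproduce_tables()` recomputes the published
group summaries from packaged per-subject fixtures, rounding means to 2
decimals and p-values to 4, half-up, to match printed precision; the
trained group is subjects S1–S5, untrained S6–S10.

## The synthetic session generator

`simulate_session()` emulates exactly the structure the pipeline
assumes:

* an ongoing mu oscillation (default 10 Hz, 6 µV amplitude, random phase
  per channel per trial) on all 21 channels;
* from 0.5 s after cue onset (a reaction latency, with a 0.2 s ramp) the
  envelope is multiplied by `1 − effect_size` contralaterally and
  `1 + effect_size` ipsilaterally — ERD as a multiplicative envelope
  change of an ongoing rhythm, the standard ERD/ERS model — while
  midline channels stay unmodulated;
* white Gaussian background noise (default sd 4 µV), with a 1/f "pink"
  option to stress the filters;
* artifact trials (probability `p_artifact`) get 3–6 random channels
  inflated to `artifact_factor` (default 20) times the nominal channel
  variance. Artifacts are channel-localized deliberately: that is what
  electrode pops and muscle bursts look like, and it is also the regime
  in which a pooled-percentile threshold is informative — inflating all
  21 channels of 15% of trials would push the 90th percentile itself
  into the artifact cluster and defeat any percentile rule;
* EOG traces are Gaussian noise (sd 10 µV) plus, for blink trials, a
  biphasic deflection. Ordinary (EOG-run) blinks draw amplitudes from
  1.0–1.3 × `blink_amp`; deliberate calibration blinks are 1.5× stronger
  (`cal_blink_gain`) — a subject vetoing a trial blinks hard, and the
  threshold (a *mean* of ordinary blink features) would otherwise miss
  half of the deliberate blinks;
* every trial derives its own RNG stream from the session seed, so any
  single trial is reproducible without regenerating the session
  (`ground_truth` records each trial's seed and injected flags).

Default `effect_size` is 0.4; the protocol description gives no
subject-level ERD magnitudes, so this is a free parameter chosen to
represent a moderately competent subject (test conditions use 0.6 for
"clearly separable", 0.5 with low noise for feedback checks, and 0 for
null controls).

What the generator does *not* model: volume-conducted correlated
backgrounds, non-stationary drifts across runs, eye-movement leakage
into the EEG channels, subject adaptation in response to feedback, or
realistic forward-modeled topographies. Passing tests therefore show
that the implementation recovers the structure it assumes — lateralized
envelope modulation under additive noise — not that it will attain any
particular accuracy on recorded EEG.

## Numerical choices and degenerate inputs

* Percentiles: R type 7; medians: midpoint convention.
* Covariance ridge 10⁻⁸·mean(diag); LDA pooled-covariance ridge the
  same. The ridge breaks exact congruence identities at the 10⁻⁵ level
  when covariances are nearly singular; property tests of those
  identities set the ridge to zero.
* Karcher mean: arithmetic-mean start, tangent-norm tolerance 10⁻⁹,
  max 50 iterations, last iterate returned with a warning otherwise.
* Empty sign-subsets contribute 0 to topographic scores; all-zero maps
  give score 0 for both hypotheses and the verdict "good" (the true
  class attains the tied maximum).
* Degenerate inputs error loudly rather than returning empty results:
  rejection that removes every trial, a zero within-class scatter,
  single-class CSP/LDA fits, zero-variance t-test differences.
* On-disk matrices are written with 17 significant digits, which
  round-trips IEEE doubles exactly.

## Problem sizes used in the shipped checks

The reference checks run one simulated session per condition (120
calibration + 40 testing trials), 500-trial Monte-Carlo batches for
verdict rates and artifact recovery, 200 decodes for the null control,
10,000 random topographies for the score bound and 1,000 for the
selection-rule oracle, and 10⁴ random unit vectors for the CSP
optimality check. These sizes give binomial standard errors of ~2
percentage points on the rates being asserted.
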