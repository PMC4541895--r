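---
title: "Fuzzy gait-phase detection and foot-movement recognition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy gait-phase detection and foot-movement recognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolegait)
```

This vignette documents the models implemented in `insolegait`, the
assumptions behind them, the tunable parameters and their defaults, and
the design choices made where the underlying method left the design
open. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The monitoring problem

Continuous gait analysis needs two things at once: a detector that
segments each gait cycle into its phases — loading response (LR),
mid-stance (MSt), terminal stance (TSt), pre-swing (PSw) and swing (Sw),
occupying 10/20/20/10/40% of the cycle in the canonical partition — and
a guard that recognizes *when the wearer is actually walking forward*,
so that turns, lateral steps, sitting down and similar foot movements do
not contaminate the accumulated gait parameters. The instrument is a
pair of insoles, each with four force-sensitive resistors (heel, fifth
metatarsal, first metatarsal, hallux) and antero-posterior plus vertical
acceleration, streaming at 50 Hz. Only the stance sub-phases are
identifiable from plantar pressure; swing is detected as the absence of
pressure, and its sub-phases are out of scope.

## Signal conditioning and calibration

Raw channels pass through a single-pole exponential moving average
(`low_pass_filter()`, coefficient 0.3 by default, in (0, 1]). The filter
family is a design choice: a one-pole recursion is causal, O(1) per
sample, and suits a 50 Hz stream; its output is a convex combination of
past inputs, so it cannot leave the input envelope. The coefficient
trades lag against smoothing; 0.3 damps sensor flutter while keeping the
~100 ms pre-swing transient visible.

FSRs drift and saturate: a sensor can read 0.5–1 V with the foot in the
air (sock contact) and tops out near 2.8–3.0 V rather than the 3.3 V
supply. The two-stage calibration therefore estimates each channel's
*effective* range: the first quartile of unloaded readings becomes the
minimum, the first quartile of fully loaded readings the maximum.
Quartiles interpolate linearly between order statistics (the classical
type-7 convention, exposed as `calibration_quantile_type()` so the
scheme can be swapped). Using the *first* quartile in both stages is
deliberate and conservative for the maximum — a low quantile of the
loaded readings under-reports the top of the range slightly, which only
compresses normalized values toward 1 and is absorbed by clamping.
Normalization maps `(x − min)/(max − min)` and clamps to [0, 1];
readings below zero are treated as corrupt records and rejected rather
than clamped, since a negative resistance reading indicates an
acquisition fault, not saturation.

## Fuzzy phase detection

Each normalized channel is described by two complementary fuzzy sets,

$$f_{\text{low}}(x) = \frac{1}{1 + e^{s(x - x_0)}},\qquad
  f_{\text{high}}(x) = 1 - f_{\text{low}}(x),$$

with inflection $x_0 = 0.5$ (symmetric over the domain) and slope
$s = 15$, except $s = 50$ on the toe channel: toe pressure during
pre-swing is brief and its on/off transition sharp, and the steeper
sigmoid segments PSw more cleanly. The steeper toe slope applies to
*every* rule that references the toe, not only the PSw rule — one slope
per channel keeps the complement identity
$f_{\text{low}} + f_{\text{high}} = 1$ meaningful per channel.

One rule per phase encodes the expected pressure pattern
(`default_rulebase()`):

| phase | heel | 5th | 1st | toe |
|-------|------|-----|-----|-----|
| LR    | high | low | low | low |
| MSt   | high | high | – | – |
| TSt   | low  | high | high | – |
| PSw   | low  | low | – | high |
| Sw    | low  | low | low | low |

Rules combine antecedents with the **minimum T-norm**; "don't-care"
channels are excluded from the minimum, so varying them cannot move the
grade. The min T-norm bounds every phase grade by each of its antecedent
grades, and an ideal 0/1 pressure pattern reaches a grade above 0.999
at $s \ge 15$.

The active phase per sample is the **argmax** of the five grades. The
method description says only that phases appear "with maximum
membership"; argmax without a minimum-grade threshold is our reading —
a threshold would create undefined gaps between phases, while argmax
always yields a decision. Exact ties keep the previously active phase
(hysteresis), falling back to cycle order at the first sample.
Consecutive same-phase samples merge into events; an optional debounce
(`min_duration_ms`, default 0 = off) absorbs sub-threshold events for
very noisy streams and is off in every shipped test. Each foot runs an
independent detector instance.

For duration analysis a cycle starts at each LR onset (initial contact).
Each complete cycle's measured per-phase durations are compared with the
reference durations computed from *that cycle's own* total time via
$\text{GPhaseTime} = \text{GPhase\%}/100 \times \text{GCycleTime}$, and
differences are averaged across cycles; positive means overestimation.
Incomplete cycles are excluded with a warning rather than an error, as
trial boundaries routinely truncate a cycle.

## Feature extraction

Twelve ring buffers (8 FSR + 4 acceleration channels) hold the most
recent 128 samples (~2.56 s at 50 Hz); no feature vector is emitted
during the 127-sample warm-up. Per buffer, three features:

- **F1** time-domain mean,
- **F2** root-mean-square,
- **F3** dominant non-DC frequency (Hz) from a 128-point FFT
  (bin width 50/128 ≈ 0.39 Hz; a flat spectrum returns the 0 Hz
  sentinel).

The authoritative trio is not recoverable from the method's published
description, which specifies only that features span the time and
frequency domains; mean/RMS/dominant-frequency is our reconstruction
and sits behind a fixed ordering (`feature_names()`) so it can be
replaced wholesale. No window precedes the FFT (rectangular), matching
the description's silence; a Hann option exists for users who prefer
lower leakage at the cost of peak smearing.

Feature 37 encodes gait dynamics symbolically: the last four *phase
activations* (changes of active phase, not frames) as a base-10 number
with digit map LR=1 … Sw=5, oldest first — MSt,TSt,PSw,Sw → 2345.
The digit map and order are our choice (cycle order); only consistency
between training and inference matters to the classifier. The left
foot's sequence is used by default (configurable): the code is computed
once per sample and a single foot keeps it deterministic. Repeat
activations (e.g. MSt–TSt–MSt) are stored verbatim.

Because raw feature scales differ by orders of magnitude (pressures in
[0, 1], frequencies in Hz, the sequence code in the thousands), features
are z-scored with training statistics before PCA; the statistics are
stored in the model document and reapplied at prediction time.

## PCA and the Gaussian naive Bayes

PCA uses the scatter matrix $S = \sum_j (x_j - m)(x_j - m)^\top$
(n × population covariance) and keeps the $I$ eigenvectors of largest
eigenvalue; $I = 22$ is the default operating point, the plateau of the
feature-count sweep. Numerical contract: symmetric eigensolver only,
eigenvalues clipped to zero above a −1e−10 relative tolerance, and a
deterministic sign convention (largest-magnitude component positive) so
refits are reproducible. The projection is applied to *centered*
samples, $y = W^\top(x - m)$, although the uncentered form is available
(`center = FALSE`): for the downstream Gaussian classifier the two are
equivalent — a common shift moves every class mean equally — but
centering matches the frame in which $S$ is computed.

The classifier assumes class-conditional feature independence with
Gaussian marginals. Per class and feature, the maximum-likelihood
estimates are the class mean and the **1/n** (population) standard
deviation; whether an unbiased 1/(n−1) estimator was intended by the
original formulation is not determinable, so 1/n is the default with
`variance = "unbiased"` behind a switch — at n = 1200 per class the
difference is negligible. A variance floor (1e−9, standardized units)
guards features that are constant within a class, such as the phase
sequence code during static activities. All scoring is in the log
domain; reported posteriors are the max-subtracted softmax of the
log-scores under equal priors and sum to 1 within 1e−12. Exact score
ties resolve to the lowest class index in the fixed activity ordering.

## The synthetic simulator

The simulator replaces human trials. What it emulates:

- **Walking forward**: per cycle, FSR envelopes follow the rule-base
  pressure patterns on the 10/20/20/10/40 schedule — heel loaded in
  LR/MSt, fifth metatarsal through MSt/TSt, first metatarsal peaking in
  TSt, toe in PSw, nothing in Sw — with raised-cosine ramps (default
  60 ms) between levels, modeling the soft, continuous transitions of
  real plantar loading (square pulses would defeat the point of fuzzy
  transitions). Don't-care channels carry plausible intermediate levels
  (partial first-metatarsal load in MSt/PSw, late toe loading in TSt).
  Feet are half a cycle out of phase; accelerations are cycle-locked
  sinusoids. Default cadence 100 steps/min → 1.2 s cycles, typical
  adult pace; Gaussian noise at 5% of the normalized range by default.
- **Walking backwards** plays the sequence in reverse (toe-to-heel) and
  flips the mean forward acceleration.
- **Turning** uses a slow 2.56 s pivot cycle with the inner foot
  partially unloaded; **lateral walking** pulses the whole foot at an
  exact spectral bin (0.78 Hz) with strong side asymmetry and little AP
  acceleration; **sitting down / standing up** are monotone sigmoidal
  load transfers with opposite AP offsets and a vertical transient.
- Simulated voltages stay inside each sensor's electrical range, so the
  quartile calibration brackets them and normalization round-trips.
- Every stream is seeded; identical parameters reproduce streams
  bit-for-bit, and the training corpus derives independent per-activity
  seeds from one master seed.

What it does *not* emulate: biomechanically validated force magnitudes,
inter-subject and stride-to-stride variability, sensor hysteresis and
temperature drift, foot-size misfit, or pathological gait. Passing
tests therefore demonstrate that the algorithms are implemented
correctly and behave as designed on signals with the documented
structure — not that the classifier reaches any particular accuracy on
recordings from real subjects, whose class-conditional feature
distributions are far less Gaussian and less separated than the
simulator's.

## Evaluation conventions

Cross-validation splits each class's samples into six contiguous blocks
— deterministic, no shuffling, since the streaming features of adjacent
samples are heavily correlated and a shuffled split would leak windows
across folds. Standardization, PCA and the classifier are refitted per
fold. The feature-count sweep covers 5–37 retained dimensions.
Recognition percentages weight each prediction by its holding time (the
interval to the next prediction; the last gets one median period), so
they always sum to 100 across the eight activities. Trial summaries use
the **population** (1/n) standard deviation — the convention that
reproduces the bundled reference tables' printed dispersions — and
display rounding of whole milliseconds or two decimals for percentages;
all comparisons in tests use unrounded values.

Problem sizes used by the shipped tests: the default corpus is 1200
feature vectors per activity (9600 × 37, from ~27 s of signal per
activity), with a 150-per-class corpus for the lighter distributional
checks; the noiseless detector-agreement runs use 10 cycles per foot.
These sizes were chosen as the package's standard experiment scale.

## Known limitations

- Swing sub-phases (ISw/MSw/TSw) are not segmented; that requires
  angular-rate sensing the pressure rules cannot provide.
- The demarcator has no minimum-confidence threshold: it always names
  a phase, even under pressure patterns matching no rule well (all
  grades small). Downstream code can inspect the membership stream if
  abstention is needed.
- The phase-sequence code is a categorical quantity modeled by a
  Gaussian; this works because it is near-constant within each activity
  but is statistically unprincipled in general.
- The reference-cycle comparison assumes the canonical phase split of
  healthy adult gait; it is a descriptive baseline, not a clinical
  norm.
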