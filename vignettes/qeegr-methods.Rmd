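---
title: "Quantitative EEG analysis of post-resuscitation recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG analysis of post-resuscitation recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegr)
```

## The problem

After resuscitation from cardiac arrest, cortical electrical activity recovers
through a stereotyped sequence: an *isoelectric* (flat) period, a
*burst-suppression* period in which high-amplitude bursts punctuate a
near-flat background, and finally *continuous background activity*. How fast
an animal (or patient) moves through this sequence, how often bursts occur
while it lasts, and how "disordered" the restored background rhythm is are
all informative about the severity of hypoxic-ischemic brain injury and about
later neurological outcome, particularly when therapeutic hypothermia is
applied early after the return of spontaneous circulation (ROSC).

`qeegr` implements this quantitative analysis for two-channel rodent EEG:
burst detection, three-class epoch classification, recovery metrics, and
spectral entropy of the band-power distribution — plus the outcome-statistics
layer such studies use (neurologic deficit scoring, two-sample tests,
survival analysis, correlation and prognostic logistic regression) and a
synthetic generator so every stage can be validated by parameter recovery
against known ground truth.

## Signal model and conditioning

Records are two bipolar channels in microvolts at a nominal 300 Hz, with time
origin at ROSC. `condition()` applies the acquisition passband (0.3–70 Hz)
digitally: a second-order Butterworth high-pass and a fourth-order low-pass,
each run forward–backward (zero phase) so burst onsets are not delayed by
group delay. The record is reflection-padded before filtering because the
0.3 Hz corner has a multi-second transient that would otherwise contaminate
the record edges. A mid-band sinusoid passes with less than 1% amplitude
error; a 100 Hz tone at 300 Hz sampling is attenuated to below 10% RMS.
If the sample rate cannot represent a 70 Hz corner the corner is clamped
below Nyquist with a warning.

## Burst detection and epoch classification

The burst definition follows the standard operational rules for
post-resuscitation rodent EEG: bursts must exceed **10 µV** rectified
amplitude **on both channels**, and are separated by interburst intervals of
at least **0.5 s** of sub-threshold activity. Several details are left open
by that verbal definition; the package resolves them as follows.

* *Amplitude measure.* Rectified (absolute) amplitude of the conditioned
  signal, with a 10 ms debounce: sub-threshold dips shorter than 10 ms are
  absorbed into an episode, and supra-threshold blips shorter than 10 ms are
  ignored as not visible. A burst must last at least 50 ms.
* *Both-channel rule.* A candidate event needs overlapping supra-threshold
  intervals on the two channels; the event extent is the union of the two
  overlapping intervals.
* *Merging.* Events separated by less than 0.5 s of sub-threshold signal are
  merged, so surviving interburst gaps always respect the 0.5 s rule.
* *Visibility.* "No visible activity" is operationalized per-sample: an
  epoch is isoelectric when neither channel has any supra-threshold episode
  lasting at least the debounce time. We deliberately do not use a sliding
  peak-to-peak criterion: with a realistic sub-threshold background of
  2 µV RMS, the expected 0.1 s peak-to-peak range is already ~8 µV and
  crosses 10 µV frequently by chance, whereas the probability that any
  single sample exceeds 10 µV (5 standard deviations) over a full 60 s epoch
  stays around 1%. The per-sample rule therefore makes the isoelectric label
  stable exactly in the regime where it is needed.

Nonoverlapping 60 s epochs anchored at the record start are then classified:

* **isoelectric** — no visible activity on either channel;
* **burst suppression** — at least one detected burst overlaps the epoch
  *and* the epoch contains a suppression segment (both channels
  sub-threshold) of at least 0.5 s;
* **continuous** — otherwise.

A trailing partial epoch is dropped, not padded.

## Recovery metrics

* `burst_onset_time()` — onset of the first detected burst, minutes from
  ROSC; missing when no burst exists. We report the first burst *event*, not
  the first burst-suppression epoch, because the onset of bursting is a point
  event while epoch labels are 60 s quantized.
* `recovery_time()` — start of the first epoch from which every subsequent
  labeled epoch is continuous. Recovery is treated as a single time point,
  so a momentary relapse into burst suppression postpones it (persistence
  rule); without this rule the quantity would be ill-defined on records that
  flicker at the transition.
* `burst_frequency()` — burst onsets per time bin divided by bin width,
  bursts/min. The default bin is 10 min over the burst-suppression period
  (1 min in the pipeline's compressed demo timeline); bin width is a
  parameter everywhere.

## Spectral entropy

For each 60 s epoch and channel, a Welch averaged periodogram is computed:
10 s segments with 50% overlap, linear detrend and a Hanning window per
segment, one-sided PSD scaled so that its integral equals the mean power
(Parseval-consistent). 10 s segments give 0.1 Hz resolution, enough to
resolve the 0.5 Hz lower band edge; segment length and overlap are
configurable, and `segment_s = 60` reproduces the single-periodogram variant
(the two agree within 0.03 entropy units on stationary synthetics once
averaged over epochs).

Band powers are the PSD integral over delta (0.5–4 Hz), theta (4–8 Hz),
alpha (8–13 Hz) and beta (13–30 Hz), with half-open bins `[low, high)` so
shared edges are counted once. With `X_i` the power in band *i*,

$$p_i = \frac{X_i}{\sum_{j=1}^{N} X_j}, \qquad
SE = \frac{-\sum_{i=1}^{N} p_i \log_2 p_i}{\log_2 N}, \quad N = 4,$$

with `0·log2(0) = 0`. SE is 1 when power is spread uniformly across the four
bands and 0 when a single band dominates; it is invariant to amplitude gain
and to band permutation, and moving probability mass from a low-power band
to the dominant band can only decrease it. A flat epoch (`sum(X) = 0`) has
no defined distribution, so SE is reported missing rather than 0 — flat
epochs are isoelectric and excluded from entropy summaries anyway, which are
conventionally restricted to epochs labeled continuous. Useful analytic
anchors: uniform `p` gives SE = 1; `p = (0.5, 0.25, 0.125, 0.125)` gives
exactly 0.875; a white-noise (flat-PSD) signal gives band probabilities
proportional to bandwidth, `p = (3.5, 4, 5, 17)/29.5`, hence SE = 0.824.

## The synthetic generator

`generate_recording()` builds records with known ground truth:

* *Isoelectric stage* — Gaussian noise, default `suppression_sigma = 2` µV,
  chosen against the Gaussian extreme-value bound so the peak amplitude of a
  60 s epoch stays below the 10 µV visibility threshold with probability
  above 0.99.
* *Burst-suppression stage* — bursts arrive as an inhomogeneous Poisson
  process with a piecewise-linear rate (bursts/min): the event count is drawn
  from Poisson(∫rate) and event times are sampled with density proportional
  to the rate, then onsets closer than 0.6 s to the previous burst's offset
  are shifted forward to the first admissible time (so bursts remain
  individually resolvable under the 0.5 s interburst rule without biasing
  the count). Each burst is
  band-limited (1–16 Hz) noise under a Tukey envelope, normalized to a 75 µV
  peak by default, and *shared across both channels* (the detection rule
  demands co-occurrence) over independent per-channel background noise.
  Burst amplitude and duration statistics are not constrained by published
  data; the defaults (0.15–0.5 s, 75 µV) are stated choices, not estimates.
* *Continuous stage* — a sum of four independent band-limited Gaussian noise
  components with configured power fractions and total RMS, independent
  across channels. The default fractions are the flat-spectrum profile
  `(3.5, 4, 5, 17)/29.5` (SE = 0.824, matching typical healthy-baseline
  entropy); the default cohort uses 30 µV RMS so that restored activity is
  unambiguously visible against the 10 µV threshold.

The generator logs its ground truth on the record: the stage boundaries and
the burst event log. Two boundaries deserve care. The burst-suppression →
continuous boundary `bs_end` is realized exactly as configured. The
isoelectric → burst-suppression boundary, however, only *manifests* at the
first burst, which lags the nominal stage start by a random (exponential)
wait; the generator therefore logs both the nominal parameter and the
realized boundary (the first burst it placed), and validation compares
detector output against the realized boundary — the nominal one is a rate
parameter, not an observable event time.

`generate_cohort()` draws per-animal stage boundaries, burst-rate ramps and
band fractions from two arm-level distributions (a treated arm with earlier
onset, earlier recovery, steeper burst-rate ramp and flatter spectrum, and a
control arm), derives each animal's record from a per-animal seed obtained
from the master seed by a fixed counter scheme (`(7919·seed + 104729·i) mod
2^31 − 1`), and simulates outcomes: a latent deficit severity on the logit
scale (arm intercept + standardized true recovery time + day effect + noise)
is thresholded into the seven neurologic-deficit-score categories at 1/3 and
2/3 severity; death occurs per day with probability
`plogis(death_intercept + death_slope · NDS)`, a total of 500 (brain death)
being fatal by definition, and survivors are censored at 96 h. Setting
`death_scale = 0` disables death entirely.

The compressed default timeline (600 s records, isoelectric ends ~90 s vs
~130 s, burst suppression ends ~300 s vs ~420 s) preserves the structure of
a 6 h experiment at desk scale; full-length synthesis is just a matter of
passing larger durations. The acceptance studies use the 2 × 10 compressed
cohort, which runs in well under a minute.

What the generator does **not** emulate: realistic EEG biophysics
(1/f background, spindles, topography), artifacts and electrode noise,
seizure or epileptiform patterns, and any physiological coupling beyond the
monotone links configured above. Passing parameter-recovery tests therefore
demonstrates that the analysis recovers the *defined* structure, not that it
is robust to everything real recordings contain.

## Outcome statistics

* `nds_total()` validates each of the seven category scores against its
  allowed set (consciousness 0/50/100, respiration 0/50/100, cornea reflex
  0/20/40, cranial/gag reflex 0/15/30, auditory reflex 0/15/30,
  motor/sensory 0/50/100, behavior 0/50/100) and totals them; the scale
  spans 0 (no deficit) to 500 (brain death).
* `welch_t_summary()` / `welch_t_raw()` compute the two-sided two-sample t
  test from summaries or raw data. The unequal-variance (Welch) form with
  Satterthwaite degrees of freedom is the default: it is the form that
  reproduces the published group comparisons this package recomputes in its
  acceptance suite, including the degenerate case of a zero-variance arm,
  where the Satterthwaite formula reduces to `n − 1` degrees of freedom of
  the other arm (e.g. a 500 ± 0 NDS arm gives df = 9 against n = 10). The
  pooled form is available behind a flag. The raw-sample version is defined
  as the summary version applied to the samples' own moments, so the two can
  never disagree.
* `fisher_exact_2x2()` — two-sided Fisher's exact test by the
  sum-of-smaller-probabilities rule (delegated to `stats::fisher.test`; the
  test suite verifies it against an independent exhaustive hypergeometric
  enumeration for every 2×2 table with total ≤ 20). An empty margin returns
  p = 1.
* `spearman_cor()` — Pearson correlation of mid-ranks with the t
  approximation for the p value; constant input yields a missing
  coefficient.
* `logistic_single()` — one predictor per model, maximum likelihood via
  `glm`, Wald test on the slope; complete separation is detected and flagged
  rather than silently reported as a huge converged coefficient.
* `km_logrank()` — Kaplan–Meier product-limit curves per arm with censoring
  at 96 h, and the log-rank chi-square (1 df) with standard tied-risk-set
  handling (day-resolution survival times make heavy ties the norm). With no
  events anywhere the statistic is undefined and reported missing.
* `twoway_anova_posthoc()` — sequential sums of squares for group, time and
  interaction from `lm`, plus per-time Welch comparisons as post hoc tests.
  Post hoc p values are **unadjusted by default**, matching common practice
  in this literature; Bonferroni/Holm adjustment is available via
  `adjust=`. Time points with an empty cell are excluded with a warning.

No multiple-testing adjustment is applied anywhere by default.

## Calibration choices

Type-I calibration of the two-sample tests is part of the test suite (1000
null replicates each, nominal α = 0.05, acceptance band 0.03–0.07). For the
Welch t the null is two Gaussian samples of 10. For Fisher's exact test the
null design matters: the test is conservative on discrete tables, with exact
size 0.020 at n = 20 per arm and 0.035 at n = 50 (computed by enumeration).
The calibration uses two Binomial(150, 0.5) arms, where the exact size is
0.043, so that a 1000-replicate Monte Carlo estimate sits inside the band
with comfortable margin. This choice was made by analytic enumeration before
the tests were written, not by adjusting to test outcomes.

## Numerical and degenerate-input choices

* Welch segments are linearly detrended individually; the window power
  normalization uses `sum(w^2)`.
* Band integration uses half-open bins, so the 4 and 8 Hz edges belong to
  the upper band only.
* Band-limited noise is synthesized by Fourier masking at a 2/3/5-smooth
  length (then truncated), keeping the FFT fast for arbitrary stage
  lengths; total power is rescaled to the target exactly.
* Flat epochs: SE missing, never 0. Empty burst lists: onset missing.
  Records that never settle into continuous activity: recovery missing.
* EDF export quantizes to 16 bits over a symmetric physical range taken
  from the data; the round-trip error is below one quantization step.
  Encoding and decoding share one affine digital↔physical map.
* All randomness flows through explicit seeds; per-animal streams are
  derived from the master seed by a fixed counter scheme, so any animal can
  be regenerated alone, and the caller's RNG state is always restored.

## Known limitations

* The epoch classifier quantizes stage boundaries to 60 s; boundary
  recovery can never be tighter than one epoch.
* The burst process enforces a 0.6 s minimum separation by shifting
  conflicting onsets forward, so the realized count stays Poisson-faithful,
  but at very high configured rates (occupancy approaching 1) onsets pile up
  and events are dropped at the stage end; the event log is the per-record
  ground truth.
* Fisher's exact test is conservative at the 2 × 10 scale typical of these
  experiments; that is a property of the test, not of the implementation.
* Baseline-versus-later entropy comparisons within one arm are implemented
  as unpaired tests; with per-animal pairing unavailable in summary form,
  paired reproduction is out of scope.
* The two-way ANOVA uses sequential sums of squares; for the balanced
  layouts it targets these coincide with the usual factorial decomposition.
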