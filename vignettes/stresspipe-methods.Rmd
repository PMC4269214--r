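---
title: "Methods: day-and-night stress assessment with stresspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-and-night stress assessment with stresspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresspipe)
```

## Overview

`stresspipe` estimates a person's perceived stress from two complementary,
unobtrusively collected modalities: smartphone behavioral logs gathered
during the workday and heart-rate-variability (HRV) measures derived from
chest-belt RR intervals recorded during sleep. The pipeline runs raw inputs
through feature extraction, correlation-based feature reduction, per-user
sequential forward selection, a three-class multinomial logit, and two
summary scores — an acute daily stress score and a chronic long-term score.
Everything is seeded and file-based, so a run is reproducible end to end.

This vignette documents the model and its assumptions, the tunable
parameters, the synthetic-data design that stands in for participant data,
and the numerical decisions a maintainer would want to know about. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The stress model

Self-reported stress is a slider score $s \in [0,1]$, segmented into ordinal
classes at 0.3 and 0.7 ($c = 0$ for $s \le 0.3$, $c = 2$ for $s \ge 0.7$,
moderate in between). If the score were uniform, the moderate band would be
the best blind guess at 40 % — the chance baseline of the three-class
problem.

The classifier is a multinomial logistic regression with reference class 0:
for $i \in \{1, 2\}$, $\log(p_i/p_0) = \beta_{0,i} + \sum_j \beta_{j,i} x_j$.
We fit it by full Newton iteration on the *mean* negative log-likelihood
plus a ridge penalty $\lambda\sum\beta^2$ on the non-intercept coefficients
($\lambda = 10^{-4}$ by default, configurable). Three choices deserve
explanation:

* **Penalty on the mean, not the sum.** Per-user training sets can be as
  small as ten days and are then often linearly separable, where the pure
  maximum-likelihood optimum diverges. Scaling the likelihood by $1/n$ makes
  the fit invariant to duplicating the data, which is both a sensible
  property and an explicit contract of `fit_logit()`.
* **Unpenalised intercepts.** As $\lambda \to 0$ the score equations then
  force the mean predicted probability vector to equal the empirical class
  distribution, a calibration property the tests assert to $10^{-6}$.
* **Deterministic everything.** The Newton iteration has no random start;
  ties in every argmax (classification, fused classification) break toward
  the lower class; a numerically singular Hessian (tiny separable fits with
  many features) gets Levenberg-style damping rather than a random restart.

Classes absent from a training fold are a real phenomenon at these sample
sizes. The fit warns and simply assigns such classes probability zero at
prediction, so a degenerate fold is still evaluated — the absent class is
unreachable, which is the honest behavior for leave-one-day-out on a user
whose days are all low-stress.

From the class probabilities, the daily stress score is
$DS = 0\,p_0 + 0.5\,p_1 + 1\,p_2$. When one modality is missing, per-modality
scores are fused as $DS = w_P DS_P + w_H DS_H$ with weights proportional to
the per-modality classification accuracies (renormalized onto the available
modality when only one exists); classification without a common model fuses
the probability vectors the same way. The long-term score is a first-order
low-pass filter $LTS_{d+1} = LTS_d + \alpha(c/2 - LTS_d)$, a contraction
with factor $1-\alpha$ that can move at most $\alpha$ per day; it is
initialized at the mean daily score of the training days. The filter
coefficient ($\alpha = 0.1$) and the relative-slider gain
($\alpha = 0.75$) are distinct parameters and are kept as separate
configuration keys `filter_alpha` and `slider_alpha`.

The relative stress questions ("compared to yesterday / last week") start at
the neutral middle of the slider; an answer covers up to 75 % of the
distance from the reference value toward 0 or 1:
$$\mathrm{out} = \begin{cases}
 \mathrm{ref} - \mathrm{ref}\,(1 - \mathrm{in}/0.5)\,\alpha & \mathrm{in} \le 0.5\\
 \mathrm{ref} + (1 - \mathrm{ref})\,((\mathrm{in} - 0.5)/0.5)\,\alpha & \mathrm{in} > 0.5
\end{cases}$$
The transform is continuous at 0.5 and monotone in the input for every
reference; the day's overall self-report averages the absolute answer with
the transformed relative answers, dropping missing ones. The yesterday
reference is yesterday's score; the last-week reference is the mean of the
last seven available scores.

## HRV features

RR intervals deviating more than 20 % from their predecessor are artifacts
(body movement, ectopic beats). Two details are underdetermined by that rule
and were fixed as follows:

* The comparison is against the previously **retained** interval, not the
  previous raw one. Comparing against the raw predecessor would let a single
  spike cascade: the beat after a +40 % ectopic deviates ~29 % from the
  spike and would be discarded too. Against the retained reference, an
  isolated spike costs exactly one beat. The filter is idempotent and the
  tests score it against the generator's known spike positions.
* Rejected beats are deleted and the beat-time axis rebuilt from the
  retained intervals. This leaves the series unevenly sampled, which is
  precisely why the spectral estimator is a Lomb–Scargle periodogram rather
  than an FFT.

The 14 features per night: sleep duration (sum of retained intervals — the
belt dump alone defines it, no wall clock needed), mean RR, SDNN, RMSSD,
pNN50 (strictly greater than 50 ms), the triangular index (beat count over
the modal height of the histogram with exactly 1000/128 = 7.8125 ms bins
aligned at integer multiples), TINN (least-squares triangular fit searched
over bin edges, padded one empty bin beyond the occupied range; a
single-bin histogram returns one bin width), approximate entropy
($m = 2$, $r = 0.2\,\mathrm{SDNN}$, Chebyshev distance, self-matches
included — the standard convention, exposed in the config), Poincaré SD1,
SD2 and SD1/SD2, and the normalized spectral features.

Variance conventions are stated so oracles are unambiguous: SDNN uses the
sample ($n-1$) denominator; Poincaré and all pooled variances (calls,
accelerometer) use the population denominator. SD1 relates to RMSSD by
$SD1 \le RMSSD/\sqrt{2}$ with equality exactly when the mean successive
difference is zero; the tests assert both the inequality and the equality
case.

The Lomb–Scargle grid spans 0.01–0.4 Hz with spacing $1/(4T)$
(oversampling 4, $T$ the span of the night); band powers are trapezoidal
integrals over VLF 0.01–0.04, LF 0.04–0.15 and HF 0.15–0.4 Hz. "Normalized"
LF and HF are LF/(LF+HF) and HF/(LF+HF) — the standard HRV normalized units,
with VLF excluded from the denominator. VLF power is computed but is not a
model feature. The estimator is the classical one with the per-frequency
offset $\tau$; on a uniform grid it is evaluated with trig-recurrence
accumulators (no trigonometric calls in the inner loop), and the tests pin
it against a direct-sum implementation on irregular grids and against the
classical periodogram on evenly spaced input, where the two coincide at
interior Fourier frequencies.

Approximate entropy and the periodogram are the only compiled (Rcpp) code:
both are quadratic-cost kernels over ~25,000 beats per night.

## Smartphone features

Nineteen features per day: call count, total/mean/variance of call duration
and the incoming/outgoing count ratio (orientation chosen as
incoming/outgoing and documented in the config; undefined with no outgoing
calls); calendar event count, total and mean duration, and mean note size
(characters — the unit had to be picked, and characters are what a phone
log actually carries); relative day-over-day changes of contact, phone
number and e-mail counts (undefined when the previous count is zero);
the not-charging/charging time ratio under piecewise-constant interpolation
of the battery samples; mean and population variance of the pooled
accelerometer magnitude; total haversine GPS distance (Earth radius
6,371,000 m); the number of visited locations from DBSCAN (defaults
eps = 100 m, minimum 5 points — typical "significant place" values, since
none are prescribed); and the mean voice-response length and RMS energy.
Every division-by-zero case yields an explicit missing value; a missing
value is never silently zero, and rows missing a model's features are
dropped per model.

Two anonymization steps mirror what a privacy-preserving collection app
must do before upload. Voice recordings are sliced into 50-ms chunks and
the chunks randomly permuted within each second — unintelligible speech,
but chunk permutation conserves the sample multiset, so duration and RMS
energy (the two features the model uses) are untouched. GPS tracks are
shifted so the centroid of the visited-location centroids becomes the
origin; longitude offsets are scaled by the cosine of the reference
latitude (a local equirectangular projection), because a plain subtraction
that moves a mid-latitude track to the equator would stretch east–west
distances by tens of percent. With the projection, the distance feature is
preserved to first order (the tests require 0.1 %).

Audio features aggregate over the up-to-four daily responses by mean (sum
would confound response count with response length, which `n_calls`-style
count features already capture).

## Feature selection and evaluation

Correlation reduction pools all users: for every feature pair, Pearson r
and its two-sided p-value over pairwise-complete rows; while any pair has
$|r| \ge 0.8$ and $p < 0.01$, the member of the worst pair with the larger
mean absolute correlation to the remaining features is dropped. The
procedure is deterministic and idempotent; constant features (undefined
correlations) are kept with a warning. The thresholds are configurable —
0.8/0.01 are defaults in the spirit of flagging only strong, significant
collinearity.

Sequential forward selection runs per user on the reduced set: starting
empty, add the feature that maximizes stratified seeded 10-fold
cross-validated accuracy, stop when the best gain is not strictly positive
(`min_improvement = 0`; the tolerance exists because floating-point CV
accuracies can tie). Fold assignment is fixed once per run, so selection is
reproducible.

User-specific models are evaluated by leave-one-day-out cross-validation
for every user with at least 10 labeled nights, and the reported accuracy
is the unweighted mean over users (pooling over days would let heavy users
dominate; with the day threshold the per-user estimates are comparably
stable). The general model uses leave-one-participant-out with accuracy
pooled over held-out days. Days without an HRV recording are excluded
throughout, so all three models describe the same days. Selection runs
once per user *before* the leave-one-day-out loop — the same two-stage
order as the reference protocol. This is knowingly optimistic (the held-out
day influenced which features were selected); re-selecting inside every
fold would remove the bias at roughly n-fold the cost, and the pipeline's
structure would admit it, but the two-stage order is what the package
reproduces.

## The synthetic-data generator

No participant data ship with the package; the generator produces all three
input kinds with controllable statistical structure and a known ground
truth, which is what the test suite and the acceptance script score
against.

* **Nights.** $RR_k = \mu + A_{LF}\sin(2\pi f_{LF} t_k) +
  A_{HF}\sin(2\pi f_{HF} t_k) + \varepsilon_k$ with $t_k$ the cumulative
  beat time, Gaussian beat noise, and ectopic beats injected at a stated
  rate as ±40 % spikes whose positions are returned. Defaults: 6 h at mean
  RR 1000 ms, LF modulation 30 ms at 0.1 Hz, HF 20 ms at 0.25 Hz, noise
  10 ms, 1 % ectopics — plausible values for healthy adult sleep. The
  modulation rides on the beat-time axis, not real time; that is adequate
  for band-dominance and filter-recall tests and is stated as such.
* **Phone days.** Poisson calls with log-normal durations, Poisson calendar
  events, contact snapshots, a monotone battery discharge with one charging
  block, accelerometer windows every 5 min for 30 s around 1 g, GPS dwell
  clouds at configurable cluster centers joined by traversal points, and
  white-noise voice responses of known RMS. Event times stay inside the
  08:00–20:00 day window.
* **Cohorts.** Per user-day, standardized latent values for six effect
  features (LF/HF, SD1/SD2, sleep duration, RMSSD, call count, audio
  length) feed a ground-truth logit (class-2 slopes twice the class-1
  slopes — an ordinal, strong signal); the class is sampled from the
  implied probabilities and the self-report drawn uniformly inside that
  class's score band, so the mapped label equals the sampled class exactly
  and label noise remains a separate, optional knob. All other features of
  the battery are independent noise at realistic levels. In raw mode the
  generator additionally writes the full `rr/`, `days/`, `reports/` input
  tree with night and phone parameters tied to the day's class, so the
  end-to-end pipeline sees a recoverable signal.

What the generator does **not** emulate: physiological sleep architecture
(stages, cyclic LF/HF shifts), cross-feature dependence beyond the planted
effect (real HRV features are mutually correlated; here the non-effect
features are independent by construction), realistic speech, and label
noise. Passing tests therefore demonstrate that the pipeline recovers known
structure of this kind — not that real smartphone or HRV data carry that
structure, and not the accuracy level attainable on any real cohort.

## Problem sizes and runtime choices

The test suite and acceptance script use scaled study conditions chosen to
exercise every stage with comfortable statistical margins: cohorts of 10
users × 30 days for model recovery and the permutation-null check, 20
four-hour nights for spectral recovery, five four-hour nights for the
artifact filter, 20 replicates for selection sanity, and a 3-user raw
cohort for end-to-end determinism. The acceptance script's six accuracies
come from a strong-effect cohort, where user-specific leave-one-day-out
with per-user selection recovers the planted effect far above the 40 %
baseline; the qualitative ordering (HRV-only above phone-only, combined
best, general model weaker than user-specific) matches what one expects
when effects are user-consistent in the latent features.

## Known limitations

* The 20 % artifact rule is a blunt instrument: it misses ectopics smaller
  than the threshold and discards genuine sudden changes; no ectopic-beat
  classification is attempted beyond it.
* Feature selection before (not inside) the outer cross-validation inflates
  user-specific accuracies; see above.
* Missing single features are dropped row-wise per model rather than
  imputed; missing whole modalities are the designed-for case and use the
  fusion path.
* The evaluation treats the three classes as nominal; the ordinal structure
  (a low/high confusion is worse than low/moderate) is not scored.
* The slider transform and combined daily input are implemented and tested,
  but the evaluation protocol uses the absolute question's score only.
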