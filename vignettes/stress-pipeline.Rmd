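---
title: "From pulse and breathing traces to a directional stress score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pulse and breathing traces to a directional stress score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtstress)
```

## The measurement problem

Patients receiving radiotherapy can be acutely stressed on the treatment
couch, and acute stress has physical consequences for treatment delivery:
muscle tension degrades setup reproducibility, and irregular breathing
directly compromises respiratory-gated delivery. `rtstress` implements a
complete analysis chain for quantifying that stress from a finger
photoplethysmogram (PPG) worn from the waiting room through the treatment
session, and for relating it to breathing-cycle irregularity recorded by a
gating system.

The chain is: clean the raw PPG and cut comparable analysis windows;
detect heartbeats and form normal-to-normal (NN) intervals; compute seven
heart-rate-variability (HRV) features per window; compare the waiting-room
("before") window with the on-couch ("during") window feature by feature;
summarize the comparison as a quantized stress score and a binary call;
predict the during-treatment changes from waiting-room data with baseline
multi-label classifiers; and regress breathing irregularity on the score
with a clustered repeated-measures model.

Because the patient recordings such a study rests on are not publicly
available, the package ships a synthetic cohort generator whose outputs have
the statistical structure each stage assumes. Every stage is exercised and
tested against that generator.

## Analysis windows

Both phases use 5 minutes of signal beginning 2 minutes after the phase
mark (`segment_phases()`, half-open windows `[start, start + 300 s)`). The
2-minute stabilization gap exists because walking into the room and lying
down transiently elevate heart rate for reasons that have nothing to do
with psychological stress; a phase with less than 7 minutes of recording is
rejected with an error naming the phase. Five minutes is the canonical
short-term HRV window: long enough to resolve the low-frequency band,
short enough to fit a waiting-room stay.

## Artifact handling

`remove_artifacts()` updates a per-sample validity mask and never alters
sample values. Three rules:

* **flatline** — variance below `1e-8` over 2-second blocks (a dropped
  sensor reads constant);
* **clipping** — three or more consecutive samples pinned at the trace
  extrema (saturation);
* **amplitude outlier** — more than 5 robust scale units from a rolling
  10-second median. The scale unit is the global IQR rather than the MAD:
  a clean PPG spends most of its time near baseline with brief systolic
  excursions, so its MAD is far smaller than the pulse amplitude and would
  flag every heartbeat, while the IQR spans the normal pulse excursion.

Masked spans are dilated by 0.5 s so burst edges are covered, and a fully
masked trace raises an "unusable segment" error — such recordings should be
excluded, not analyzed. Beats falling inside masked spans are discarded
downstream.

## Beat detection from the second derivative

`detect_beats()` band-passes the signal to 0.5–8 Hz, then takes a
Savitzky–Golay smoothed second derivative. Raw double differentiation
amplifies high-frequency noise by the square of frequency, so smoothing is
not optional; the polynomial filter differentiates and smooths in one pass
(window 0.13 s, cubic). Beats are local maxima of the *negative* curvature:
the systolic upstroke is where the pulse wave bends hardest, and on the
acceleration signal that extremum is sharp even when the pulse peak itself
is broad.

Candidates must exceed an adaptive prominence threshold — a fraction (0.3)
of the rolling 95th-percentile curvature over 10-second blocks — because an
absolute threshold cannot survive differences in sensor gain. A 0.3 s
refractory period (heart rate ≤ 200 bpm) suppresses double-detections, with
the stronger candidate winning. On clean synthetic PPG at the generator's
default noise the detector recovers over 99% of beats within 20 ms, and the
tests require exactly that.

`beats_to_nn()` forms successive differences in ms and applies two standard
removal rules: intervals outside [300, 2000] ms (a missed beat makes one
long interval, a false detection makes two short ones) and intervals more
than 20% from an 11-interval rolling median (ectopy). The constructor
itself is permissive about series length so that small didactic fixtures
work; the ≥ 30-interval floor for trustworthy HRV is enforced where the
features are computed.

## The seven HRV features

`compute_hrv_features()` returns, per window:

| feature | definition | stressful direction |
|---|---|---|
| HR | 60000 / mean(NN) bpm | increase |
| SDNN | sample SD of NN (ms) | decrease |
| RMSSD | RMS of successive NN differences (ms) | decrease |
| pNN50 | % successive differences > 50 ms | decrease |
| HF | power in 0.15–0.4 Hz (ms²) | decrease |
| LF/HF | 0.04–0.15 Hz power / HF | increase |
| TP | total power 0.004–0.4 Hz (ms²) | decrease |

Numerical choices, each deliberate:

* **SDNN uses the n−1 denominator**, the dominant convention in HRV
  software; with it the alternating ±50 ms test series has the exact
  closed-form SD `sqrt(n/(n-1))·50`.
* **Spectral estimation**: the tachogram (NN value against the time of the
  interval-ending beat) is resampled at 4 Hz by cubic spline, mean-removed,
  and analyzed with a Welch estimator using Hann windows of half the series
  span (never shorter than 120 s) at 50% overlap — for a 300 s window that
  is three 150 s segments. Band powers are one-sided-density sums times the
  bin width, so the total integral matches the series variance (Parseval);
  the tests require agreement within 10%.
* **The LF band is 0.04–0.15 Hz**, the long-standing task-force convention;
  the ratio needs a definition of LF even where only the ratio is reported.
* **TP integration starts at the first positive frequency bin.** With a
  300 s window the nominal 0.004 Hz lower edge sits at the resolution
  limit; claiming power "at 0.004 Hz" from such a window would be
  numerology, so the implementation integrates from the first resolvable
  bin and says so here.
* **A zero-HF window makes LF/HF undefined**, returned as `NA` with a flag
  (`lf_hf_defined = FALSE`), never as a substituted infinity.

## The directional stress score

`label_changes()` marks each feature `TRUE` when the during-treatment value
moved *strictly* in its stressful direction. Exact ties count as **not**
stressful: ties have measure zero for continuous features, so the rule only
matters for degenerate inputs, and the conservative choice makes "nothing
changed" score 0 rather than something arbitrary. An undefined LF/HF in
either window gives a `FALSE` label plus a data-quality flag — guessing a
direction silently would be worse.

The score is `100·k/7` for `k` true labels, rounded **half-up** to two
decimals, so the only attainable values are 0, 14.29, 28.57, 42.86, 57.14,
71.43, 85.71, 100. Half-up rounding (rather than R's round-half-even) makes
the emitted bins string-match the conventional presentation of such scores.
The binary call is "yes" strictly above 50%; with seven labels a score of
exactly 50 is unattainable, which the code asserts rather than assumes.

```{r score}
labels <- c(hr = TRUE, sdnn = TRUE, rmssd = TRUE, pnn50 = TRUE,
            hf = TRUE, lf_hf = TRUE, tp = FALSE)
stress_score(labels)
```

## Predicting during-treatment changes

`build_dataset()` assembles the eight input variants: the seven
before-treatment features always, plus every subset of {age, sex, day}
(Type 1 = none … Type 8 = all three; sex encoded 0/1, day as integer).
Targets are the seven during-treatment labels, making this a multi-label
problem.

Model families (`fit_predict()`): one CART per label, one random forest per
label, one RBF-SVM per label, an Elman recurrent network, and a single-head
self-attention network. The two sequence models read the input vector as an
ordered univariate sequence in the fixed feature order — a tabular-to-
sequence mapping has to be chosen somehow, and a fixed order at least makes
it reproducible; this is a known arbitrary point. They are implemented
directly in R (tiny dimensions make this fast), trained full-batch with
Adam on the binary cross-entropy, and their analytic gradients are verified
against finite differences in the tests. Continuous inputs are z-scored on
the training split for the margin and neural models; trees get raw values.

`crossvalidate()` defaults to 10 folds with **patient-grouped** assignment,
so no patient's cases straddle a training/test boundary — repeated measures
of one patient are correlated, and splitting them inflates performance. A
plain case-level mode exists (`grouped = FALSE`) for parity with analyses
that do not state grouping; with it, 123 cases split into folds of 12 and
13.

Metrics (`evaluate_multilabel()`): the exact match ratio (all seven labels
right) plus accuracy, recall, precision and F1. Multi-label averaging is
ambiguous, so both **example-based** (per-case Jaccard accuracy, per-case
P/R/F1 averaged over cases) and **micro** (pooled over label cells; micro
accuracy is Hamming accuracy) figures are always emitted rather than
committing to an unverifiable choice. The identity EMR ≤ example-based
accuracy holds by construction and is property-tested. The binary stress
prediction is *derived* from the predicted labels through the score — it is
not a separately trained classifier — so the two evaluations stay
consistent (`evaluate_binary()`).

## Breathing irregularity

`detect_extrema()` smooths the displacement trace with a 0.5 s moving
average, finds local maxima/minima at least 1.5 s apart (breathing stays
under ~40 cycles/min), requires a local prominence (25% of the ±5 s
excursion range, judged locally so slow baseline drift cannot suppress real
cycles), refines extremum times by parabolic interpolation to beat the
sample grid, and enforces strict peak/valley alternation by keeping the
more extreme member of any same-type run.

The irregularity statistic is the mean of two standard deviations — over
peak values and valley values (amplitude irregularity, signal units), or
over peak-to-peak and valley-to-valley periods (phase irregularity,
seconds). Sample SDs (n−1) throughout, consistent with SDNN. Amplitude uses
raw extremum values, not peak-to-valley excursions: "dispersion of the
peaks and of the valleys" reads as value dispersion, and an excursion-based
variant would be a different statistic. Note the units caveat: gating
systems export displacement in device-specific units and the phase statistic
depends on whether periods are measured in seconds or samples, so absolute
irregularity magnitudes are only comparable within one acquisition setup.
The package treats units as metadata and reproduces the *statistical
structure* of the association, not any absolute magnitude.

## The association model

`associate_irregularity()` fits a marginal linear model of irregularity on
the stress predictor — the score per 10 points, or the binary call — with
patients as clusters: a Gaussian identity-link GEE with exchangeable
working correlation (moment-estimated intra-cluster correlation) and robust
sandwich covariance. The exchangeable structure is the natural default for
repeated sessions with no strong serial ordering, and the sandwich makes
the inference valid even when that working choice is wrong.

Two finite-sample corrections are applied, because cohorts of ~40 patients
are exactly where the plain sandwich is anti-conservative: the meat is
scaled by G/(G−1) (G clusters), and Wald intervals and p-values use t
quantiles with G−p degrees of freedom. In the package's own simulation
(200 replicates of 40 patients × 3 days), 95% intervals cover the
generating slope 93% of the time and retain a true null 96% of the time,
inside the tested 90–98% band. With a single cluster the function falls
back to OLS with heteroskedasticity-robust errors and a warning; with a
constant predictor (e.g. every case stressed) it reports `NA` with a
warning instead of a spurious estimate.

The implementation is checked against two independent references in the
tests: under an independence working correlation it must equal OLS with
cluster-robust (`sandwich::vcovCL`) covariance exactly, and its
exchangeable point estimates must match compound-symmetry GLS.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` produces patient-day case tables with the structure the
analysis assumes. Defaults were fixed once, as the study conditions:

* 41 patients, 1–5 measurement days each, about two thirds male, ages
  47–80;
* `p_stress = 0.5`: each feature moves in its stressful direction with
  probability one half, giving a mean of 3.5 stressful shifts out of 7 and
  an above-threshold ("yes") rate at the Binomial(7, 0.5) tail of 0.5 —
  the regime where roughly half of cases are called stressed;
* `resp_slope = 0.286` irregularity units per 10 score points, with
  intercept 8.6, patient-level SD 4 and residual SD 2.5, placing phase
  irregularity around 10 with a 3–30 spread;
* relative feature shifts of ~15%.

Feature levels are drawn from plausible resting distributions (e.g. HR
around 72 bpm, SDNN log-normal around 35 ms); during-values move
multiplicatively in the drawn direction, so ties never occur by
construction. Labels, score and binary call are computed through the
package's own scoring functions, not duplicated logic, and the tests verify
that re-assessment of a generated cohort reproduces its stored columns.

The signal-level generators are deliberately minimal. The tachogram is mean
RR plus two independent band-limited Gaussian components scaled to hit the
SDNN and LF/HF targets exactly in the continuous-time signal — the simplest
construction whose spectral split is controllable analytically. The PPG
places a two-Gaussian pulse (systolic + diastolic wave) at each beat.
Breathing cycles have a fixed-duration inspiratory rise with expiration
absorbing period variability, and level variation enters as slow
(0.03–0.1 Hz) baseline wander on a constant excursion, so period dispersion
and extremum-value dispersion — the two ingredients of the irregularity
statistic — are independently controllable.

None of this is physiological realism: there is no respiratory sinus
arrhythmia coupling the two signals, no pulse-morphology variation with
blood pressure, no apnea or cough events, and motion artifacts are additive
low-frequency bursts rather than mechanics. Passing tests therefore show
that the *algorithms* do what they claim on signals with known structure;
they do not certify performance on real sensor data, whose failure modes
are richer.

All randomness flows through one seeded stream per call (restored on exit,
so package functions never disturb the caller's RNG), and every generator
is bitwise reproducible from its seed.

## Problem sizes used by the test suite

The suite runs the full chain at the sizes the analysis targets: 300 s
windows for signal-level checks; cohorts of 41–170 patients for the
statistical properties; 200 replicates of 40 patients × 3 days for the
coverage study; 10-fold cross-validation on cohorts up to 600 cases for the
learnability/chance-level pair. These sizes were chosen to make each check
statistically meaningful at desk scale.

## Known limitations

* The stress score weights all seven features equally; weighting by
  feature reliability is an obvious refinement, deliberately out of scope.
* The quantized score makes fine-grained within-patient trends coarse; the
  per-patient normalization (`normalize_scores_per_patient()`) mitigates
  scale differences but not quantization.
* The sequence models are baselines, not tuned architectures; their value
  here is interface completeness and determinism, not state-of-the-art
  accuracy.
* Absolute irregularity magnitudes depend on unstated device units (see
  above); only relative and inferential statements transfer across setups.
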