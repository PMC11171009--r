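# rtstress

Quantifying physiological stress in radiotherapy patients from wearable
biosignals — and measuring what that stress does to their breathing.

Patients lying on a treatment couch are often acutely stressed, and stress
has delivery consequences: tense patients set up less reproducibly, and
irregular breathing degrades respiratory-gated beam delivery. `rtstress`
implements, end to end and with tests at every stage:

1. **PPG processing** — artifact masking (flatline / clipping / amplitude
   outliers), 5-minute analysis windows cut 2 minutes after each phase mark
   (waiting room vs treatment couch), heartbeat detection from the smoothed
   second derivative of the pulse wave, and NN-interval cleaning.
2. **HRV features** — the seven stress-linked indices per window:
   HR, SDNN, RMSSD, pNN50, HF (0.15–0.4 Hz), LF/HF (LF 0.04–0.15 Hz), TP
   (Welch spectrum of the 4 Hz-resampled tachogram).
3. **Directional stress score** — each feature is labelled by whether it
   moved in its stressful direction (HR and LF/HF up; SDNN, RMSSD, pNN50,
   HF, TP down) between the before- and during-treatment windows; the score
   is 100·k/7 for k stressful shifts (so quantized to
   0, 14.29, …, 85.71, 100), and a case is called stressed when the score
   exceeds 50%.
4. **Prediction** — eight input-dataset variants (before-treatment features
   plus subsets of age/sex/day), five baseline multi-label model families
   (decision tree, random forest, SVM, Elman RNN, single-head attention),
   patient-grouped 10-fold cross-validation, and both example-based and
   micro-averaged EMR/accuracy/recall/precision/F1.
5. **Respiratory irregularity** — breathing peak/valley detection and the
   irregularity statistic `(STD(peaks) + STD(valleys)) / 2` in amplitude
   and phase, related to the stress score with a patient-clustered GEE
   (exchangeable working correlation, small-sample-corrected sandwich
   errors).
6. **Synthetic cohort generator** — patient-day case tables and raw
   PPG/breathing traces with controllable stress structure, so the whole
   chain is testable without patient data.

## Worked example

Two synthetic 5-minute windows — a calm waiting-room tachogram and a
faster, flatter on-couch one — through features, labels and score:

```r
library(rtstress)

nn_before <- generate_nn_series(
  tachogram_spec(mean_hr = 65, sdnn_target = 45, lf_hf_target = 1.2), seed = 101)
nn_during <- generate_nn_series(
  tachogram_spec(mean_hr = 74, sdnn_target = 33, lf_hf_target = 1.9), seed = 102)
before <- compute_hrv_features(nn_before)
during <- compute_hrv_features(nn_during)
round(rbind(before = before[1:8], during = during[1:8]), 2)
#>           hr  sdnn rmssd pnn50      lf     hf lf_hf      tp
#> before 65.13 44.78 46.82 29.85 1105.79 818.89  1.35 1926.29
#> during 74.19 32.76 27.12  6.22  602.53 375.23  1.61  978.63

labels <- label_changes(before, during)
labels
#>    hr  sdnn rmssd pnn50    hf lf_hf    tp
#>  TRUE  TRUE  TRUE  TRUE  TRUE  TRUE  TRUE
stress_score(labels)
#> [1] 100
```

All seven features moved in their stressful direction (HR and LF/HF rose;
the five variability measures fell), so this case scores 100 and is called
stressed.

At cohort scale — generate a 41-patient synthetic cohort, summarize the
score distribution, and fit the stress–breathing association:

```r
co <- generate_cohort(cohort_config(seed = 1))
summarize_distribution(co)
#> <rt_distribution> 127 cases: 99.21% with any stress shift, 51.97% above the 50% threshold
#> # A tibble: 8 × 3
#>   score     n   pct
#> 1   0       1  0.79
#> 2  14.3     6  4.72
#> ...

associate_irregularity(co, predictor = "score10", response = "phase_irr")
#> # A tibble: 1 × 8
#>   response  predictor_kind        beta   lcl   ucl  p_value n_cases n_patients
#> 1 phase_irr stress score per 10% 0.513 0.243 0.783 0.000441     127         41
```

`beta` is the fitted increase in phase irregularity per 10 stress-score
points, with its 95% interval and p-value from the clustered
repeated-measures fit (this cohort was generated with a true slope of
0.286; the interval covers it).

A thin CLI wraps the same functions:

```sh
exec/rtstress all --seed 17 --out results/
exec/rtstress predict --dataset-type 8 --model forest --folds 10 --seed 17
```

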