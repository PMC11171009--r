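# Synthetic signal generators: tachograms, PPG waveforms, breathing traces.
# These define the study conditions every downstream stage is tested against.

#' Tachogram specification
#'
#' Targets for a synthetic NN-interval series: mean heart rate, overall
#' variability (SDNN) and the split of that variability between the
#' low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) bands.
#'
#' @param mean_hr mean heart rate in bpm, in \[30, 180\].
#' @param sdnn_target target SDNN in ms (>= 0).
#' @param lf_hf_target target LF/HF band-power ratio (> 0; ignored when
#'   `sdnn_target` is 0).
#' @param duration recording length in seconds (> 0).
#' @return a list of class `tachogram_spec`.
#' @export
tachogram_spec <- function(mean_hr = 70, sdnn_target = 40, lf_hf_target = 1.5,
                           duration = 300) {
  stopifnot_scalar_number(mean_hr, "mean_hr", 30, 180)
  stopifnot_scalar_number(sdnn_target, "sdnn_target", 0)
  stopifnot_scalar_number(lf_hf_target, "lf_hf_target", 0)
  stopifnot_scalar_number(duration, "duration", .Machine$double.eps)
  mean_rr <- 60000 / mean_hr
  # Gaussian tachogram: +-5 sd must stay inside the physiological NN range,
  # otherwise the spec cannot be realized without clipping.
  if (mean_rr - 5 * sdnn_target < 300 || mean_rr + 5 * sdnn_target > 2000) {
    abort(sprintf(
      "Unattainable spec: mean RR %.0f ms with SDNN %.0f ms would push intervals outside [300, 2000] ms.",
      mean_rr, sdnn_target), class = "rtstress_unattainable_spec")
  }
  structure(list(mean_hr = mean_hr, sdnn_target = sdnn_target,
                 lf_hf_target = lf_hf_target, duration = duration),
            class = "tachogram_spec")
}

# Band-limited Gaussian noise via random-phase inverse FFT, rescaled to an
# exact realized standard deviation.
band_noise <- function(n, fs, band, target_sd) {
  if (target_sd <= 0) return(numeric(n))
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(floor(n / 2))          # positive, non-DC, non-Nyquist bins
  in_band <- half[freqs[half] >= band[1] & freqs[half] < band[2]]
  if (!length(in_band)) {
    abort("Duration too short to resolve the requested frequency band.",
          class = "rtstress_unattainable_spec")
  }
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  amp <- complex(real = rnorm(length(in_band)), imaginary = rnorm(length(in_band)))
  spec[in_band] <- amp
  spec[n + 2 - in_band] <- Conj(amp)
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd0(x) * target_sd
}

#' Generate a synthetic NN-interval series
#'
#' Builds a continuous tachogram as mean RR plus two independent band-limited
#' Gaussian components (LF 0.04-0.15 Hz, HF 0.15-0.4 Hz) whose standard
#' deviations are chosen so the tachogram SD equals `sdnn_target` and the
#' LF/HF variance ratio equals `lf_hf_target`, then places beats by reading
#' the tachogram at each successive beat time.
#'
#' @param spec a [tachogram_spec()].
#' @param seed integer seed; the same spec and seed give identical series.
#' @return an [rt_nn()] series.
#' @export
generate_nn_series <- function(spec, seed = 1) {
  if (!inherits(spec, "tachogram_spec")) spec <- do.call(tachogram_spec, spec)
  with_local_seed(seed, {
    mean_rr <- 60000 / spec$mean_hr
    if (spec$sdnn_target == 0) {
      n_beats <- ceiling(spec$duration / (mean_rr / 1000)) + 1L
      return(rt_nn(seq(0, by = mean_rr / 1000, length.out = n_beats)))
    }
    fs_t <- 4
    n <- ceiling(spec$duration * fs_t) + fs_t * 8   # pad to cover drift
    r <- spec$lf_hf_target
    sd_lf <- spec$sdnn_target * sqrt(r / (1 + r))
    sd_hf <- spec$sdnn_target * sqrt(1 / (1 + r))
    tacho <- mean_rr +
      band_noise(n, fs_t, c(0.04, 0.15), sd_lf) +
      band_noise(n, fs_t, c(0.15, 0.40), sd_hf)
    grid <- (0:(n - 1)) / fs_t
    beats <- numeric(ceiling(spec$duration / (0.3)) + 2L)
    beats[1] <- 0
    k <- 1L
    while (beats[k] < spec$duration) {
      rr <- stats::approx(grid, tacho, xout = beats[k], rule = 2)$y / 1000
      beats[k + 1L] <- beats[k] + rr
      k <- k + 1L
    }
    beats <- beats[seq_len(k)]
    nn <- rt_nn(beats)
    if (any(nn$nn_ms < 300 | nn$nn_ms > 2000)) {
      abort("Realized intervals left [300, 2000] ms; spec is unattainable.",
            class = "rtstress_unattainable_spec")
    }
    nn
  })
}

# Two-Gaussian pulse template: systolic wave at +0.20 s, smaller diastolic
# wave at +0.48 s, evaluated at offsets `t` (s) from beat onset.
ppg_pulse_template <- function(t) {
  exp(-(t - 0.20)^2 / (2 * 0.045^2)) + 0.35 * exp(-(t - 0.48)^2 / (2 * 0.09^2))
}

#' Synthesize a PPG trace from beat times
#'
#' Places one two-Gaussian pulse (systolic + diastolic wave) at every beat,
#' adds white noise, and optionally injects high-amplitude low-frequency
#' motion-artifact bursts. The systolic-peak times (beat onset + 0.20 s) are
#' retained as ground truth for detector tests.
#'
#' @param nn an [rt_nn()] series (or numeric vector of beat-onset times in s).
#' @param fs sampling rate in Hz (>= 50).
#' @param noise_sd white-noise SD relative to the unit pulse amplitude.
#' @param artifacts optional tibble/list with `start`, `duration`,
#'   `amplitude` (relative) and optional `freq` (Hz) describing motion
#'   bursts.
#' @param phase_marks optional named phase-mark times (s), passed through.
#' @param seed integer seed for the noise.
#' @return an [rt_trace()] whose `truth` attribute carries
#'   `beat_times` (systolic peaks) and any `artifact_spans`.
#' @export
synthesize_ppg <- function(nn, fs = 100, noise_sd = 0.05, artifacts = NULL,
                           phase_marks = NULL, seed = 1) {
  if (fs < 50) abort("PPG synthesis requires fs >= 50 Hz.",
                     class = "rtstress_bad_argument")
  onsets <- if (inherits(nn, "rt_nn")) attr(nn, "beat_times") else as.numeric(nn)
  with_local_seed(seed, {
    total <- max(onsets) + 1.2
    n <- ceiling(total * fs)
    t <- (0:(n - 1)) / fs
    x <- numeric(n)
    for (b in onsets) {
      lo <- max(1L, floor((b - 0.1) * fs)); hi <- min(n, ceiling((b + 0.9) * fs))
      idx <- lo:hi
      x[idx] <- x[idx] + ppg_pulse_template(t[idx] - b)
    }
    if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
    spans <- NULL
    if (!is.null(artifacts)) {
      artifacts <- as_tibble(artifacts)
      for (i in seq_len(nrow(artifacts))) {
        a <- artifacts[i, ]
        f <- if ("freq" %in% names(a)) a$freq else 0.7
        idx <- which(t >= a$start & t < a$start + a$duration)
        x[idx] <- x[idx] + a$amplitude * sin(2 * pi * f * t[idx])
        spans <- rbind(spans, c(a$start, a$start + a$duration))
      }
    }
    rt_trace(x, fs = fs, phase_marks = phase_marks, units = "PPG (a.u.)",
             truth = list(beat_times = onsets + 0.20,
                          artifact_spans = spans))
  })
}

#' Generate a synthetic breathing trace
#'
#' Concatenates breathing cycles whose periods are drawn
#' `N(period_mean, period_sd)`, each a half-cosine rise and fall of constant
#' excursion `amp_mean`, riding on band-limited (0.03-0.1 Hz) baseline
#' wander with standard deviation `amp_sd` -- the slow displacement drift a
#' gating system sees when the patient settles. Peak and valley *values*
#' therefore both disperse with SD `amp_sd` while every cycle keeps a clean
#' excursion, so the two ingredients of the irregularity statistic (period
#' dispersion and extremum-value dispersion) are directly controllable.
#'
#' @param period_mean mean breathing period in s (> 0).
#' @param period_sd SD of cycle periods in s.
#' @param amp_mean mean cycle amplitude (signal units).
#' @param amp_sd SD of cycle amplitudes.
#' @param fs sampling rate in Hz.
#' @param duration trace length in s (>= 10 periods).
#' @param baseline constant displacement offset.
#' @param seed integer seed.
#' @return an [rt_trace()]; `truth` carries per-cycle periods, amplitudes and
#'   peak times.
#' @export
generate_resp_trace <- function(period_mean = 4, period_sd = 0.3,
                                amp_mean = 1, amp_sd = 0.1, fs = 25,
                                duration = 240, baseline = 0, seed = 1) {
  stopifnot_scalar_number(period_mean, "period_mean", .Machine$double.eps)
  if (duration < 10 * period_mean) {
    abort("Need at least 10 breathing periods of recording.",
          class = "rtstress_bad_argument")
  }
  with_local_seed(seed, {
    n_cyc <- ceiling((duration + 2 * period_mean) / max(period_mean / 3, 0.5))
    periods <- pmax(period_mean / 3, rnorm(n_cyc, period_mean, period_sd))
    periods <- periods[cumsum(periods) < duration + 2 * period_mean]
    n_cyc <- length(periods)

    n <- ceiling(duration * fs)
    t <- (0:(n - 1)) / fs
    x <- numeric(n)
    starts <- cumsum(c(0, periods))[seq_len(n_cyc)]
    # inspiration keeps a fixed duration; expiration absorbs the period
    # variability, so peak-to-peak intervals carry the full dispersion
    rise <- pmin(period_mean / 2, 0.6 * periods)
    for (i in seq_len(n_cyc)) {
      up <- which(t >= starts[i] & t < starts[i] + rise[i])
      dn <- which(t >= starts[i] + rise[i] & t < starts[i] + periods[i])
      x[up] <- amp_mean * (1 - cos(pi * (t[up] - starts[i]) / rise[i])) / 2
      x[dn] <- amp_mean *
        (1 + cos(pi * (t[dn] - starts[i] - rise[i]) / (periods[i] - rise[i]))) / 2
    }
    wander <- if (amp_sd > 0) band_noise(n, fs, c(0.03, 0.10), amp_sd) else numeric(n)
    x <- baseline + x + wander
    peak_times <- starts + rise
    rt_trace(x, fs = fs, units = "displacement",
             truth = list(periods = periods,
                          amplitudes = rep(amp_mean, n_cyc),
                          peak_times = peak_times[peak_times < duration]))
  })
}
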