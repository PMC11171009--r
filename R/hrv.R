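# The seven stress-related HRV features: time domain (HR, SDNN, RMSSD,
# pNN50) and frequency domain (LF, HF, TP, LF/HF) from an NN series.

#' Time-domain HRV features
#'
#' * HR = 60000 / mean(NN) in bpm
#' * SDNN = sample standard deviation (n-1 denominator) of the NN intervals
#' * RMSSD = root-mean-square of successive NN differences
#' * pNN50 = percentage of successive differences exceeding 50 ms
#'
#' @param nn an [rt_nn()] series.
#' @param min_intervals required series length (the usual short-term HRV
#'   floor of 30 intervals).
#' @return one-row tibble: `hr`, `sdnn`, `rmssd`, `pnn50`.
#' @export
hrv_time_domain <- function(nn, min_intervals = 30) {
  x <- nn$nn_ms
  if (length(x) < min_intervals) {
    abort(sprintf("Too few NN intervals (%d < %d) for time-domain HRV.",
                  length(x), min_intervals),
          class = "rtstress_insufficient_nn")
  }
  d <- diff(x)
  tibble(
    hr = 60000 / mean(x),
    sdnn = sd(x),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50)
  )
}

# Welch PSD with Hann windows, 50% overlap, one-sided density normalized so
# sum(psd) * df ~= var(x).
welch_psd <- function(x, fs, win_samples) {
  n <- length(x)
  L <- min(win_samples, n)
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  u <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * u)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  tibble(freq = (seq_len(nf) - 1L) * fs / L, psd = acc / length(starts))
}

band_power <- function(spec, lo, hi) {
  df <- spec$freq[2] - spec$freq[1]
  sum(spec$psd[spec$freq >= lo & spec$freq <= hi]) * df
}

#' Frequency-domain HRV features
#'
#' The NN tachogram (interval length vs time of the interval-ending beat) is
#' resampled evenly by cubic spline, mean-removed, and its Welch spectrum
#' integrated over the standard bands: LF 0.04-0.15 Hz, HF 0.15-0.4 Hz, and
#' TP from the first positive frequency bin to 0.4 Hz. `lf_hf` is `NA` (with
#' a flag) when HF is numerically zero rather than a substituted infinity.
#'
#' @param nn an [rt_nn()] series spanning at least `min_span_s` seconds.
#' @param resample_hz even-resampling rate (Hz).
#' @param window_s Welch window length (s); the default uses the longer of
#'   120 s and half the series span, so a 300 s window yields three 150 s
#'   segments at 50% overlap.
#' @param lf_band,hf_band,tp_band integration bands (Hz).
#' @param min_span_s minimum tachogram span (s).
#' @return one-row tibble: `lf`, `hf`, `tp`, `lf_hf`, `lf_hf_defined`.
#' @export
hrv_frequency_domain <- function(nn, resample_hz = 4, window_s = NULL,
                                 lf_band = c(0.04, 0.15),
                                 hf_band = c(0.15, 0.40),
                                 tp_band = c(0.004, 0.40),
                                 min_span_s = 120) {
  t <- nn$beat_time
  span <- max(t) - min(t)
  if (span < min_span_s) {
    abort(sprintf("NN series spans %.0f s; %g s required for spectral HRV.",
                  span, min_span_s), class = "rtstress_insufficient_nn")
  }
  window_s <- window_s %||% max(120, span / 2)
  grid <- seq(min(t), max(t), by = 1 / resample_hz)
  xr <- spline(t, nn$nn_ms, xout = grid)$y
  xr <- xr - mean(xr)
  spec <- welch_psd(xr, resample_hz, round(window_s * resample_hz))
  df <- spec$freq[2] - spec$freq[1]
  lf <- band_power(spec, lf_band[1], lf_band[2])
  hf <- band_power(spec, hf_band[1], hf_band[2])
  tp <- band_power(spec, max(tp_band[1], df), tp_band[2])
  hf_zero <- hf <= .Machine$double.eps * 100
  tibble(
    lf = lf, hf = hf, tp = tp,
    lf_hf = if (hf_zero) NA_real_ else lf / hf,
    lf_hf_defined = !hf_zero
  )
}

#' All HRV features for one NN series
#'
#' Composition of [hrv_time_domain()] and [hrv_frequency_domain()].
#'
#' @param nn an [rt_nn()] series.
#' @param ... passed to [hrv_frequency_domain()].
#' @return one-row tibble with `hr`, `sdnn`, `rmssd`, `pnn50`, `lf`, `hf`,
#'   `lf_hf`, `tp`, `lf_hf_defined`.
#' @export
compute_hrv_features <- function(nn, ...) {
  td <- hrv_time_domain(nn)
  fd <- hrv_frequency_domain(nn, ...)
  bind_cols(td, fd[c("lf", "hf", "lf_hf", "tp", "lf_hf_defined")])
}
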