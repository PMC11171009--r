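# Breathing-trace extrema, the irregularity statistic (mean of the peak and
# valley standard deviations), and per-patient score normalization.

#' Detect breathing peaks and valleys
#'
#' Smooths the displacement trace with a 0.5 s moving average, finds local
#' maxima/minima separated by at least `min_sep_s` (breathing stays below
#' ~40 cycles/min) and exceeding a prominence floor (a fraction of the
#' robust signal range), then enforces strict peak/valley alternation by
#' keeping the more extreme member of any same-sign run.
#'
#' @param trace an [rt_trace()] breathing trace (>= 30 s).
#' @param smooth_s moving-average width (s).
#' @param min_sep_s minimum spacing between same-type extrema (s).
#' @param prominence fraction of the robust (5th-95th percentile) range an
#'   excursion must reach.
#' @return list of class `rt_extrema`: `peak_times`, `peak_values`,
#'   `valley_times`, `valley_values`.
#' @export
detect_extrema <- function(trace, smooth_s = 0.5, min_sep_s = 1.5,
                           prominence = 0.25) {
  fs <- trace_fs(trace)
  x <- trace$value
  n <- length(x)
  if (n / fs < 30) abort("Need at least 30 s of breathing signal.",
                         class = "rtstress_bad_argument")
  k <- max(1L, round(smooth_s * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]

  rng <- diff(quantile(xs, c(0.05, 0.95)))
  if (rng <= 0) abort("Too few breathing cycles: signal has no excursions.",
                      class = "rtstress_too_few_cycles")
  # prominence is judged against the local (+-5 s) excursion so slow
  # baseline wander does not suppress genuine cycles
  w <- round(5 * fs)
  local_ok <- function(i, sgn) {
    win <- xs[max(1L, i - w):min(n, i + w)]
    span <- max(win) - min(win)
    if (span <= 0) return(FALSE)
    if (sgn > 0) xs[i] >= min(win) + prominence * span
    else xs[i] <= max(win) - prominence * span
  }

  local_ext <- function(sgn) {
    y <- sgn * xs
    cand <- which(c(FALSE, diff(y[-n]) > 0 & diff(y[-1]) <= 0, FALSE))
    cand <- cand[vapply(cand, local_ok, logical(1), sgn = sgn)]
    if (!length(cand)) return(integer(0))
    ord <- cand[order(y[cand], decreasing = TRUE)]
    kept <- numeric(0)
    for (i in ord) {
      if (!length(kept) || all(abs(trace$time[kept] - trace$time[i]) >= min_sep_s)) {
        kept <- c(kept, i)
      }
    }
    sort(kept)
  }
  pk <- local_ext(1)
  vl <- local_ext(-1)
  if (length(pk) < 3 || length(vl) < 3) {
    abort("Too few breathing cycles: need at least 3 peaks and 3 valleys.",
          class = "rtstress_too_few_cycles")
  }

  # alternation: within runs of same-type extrema keep the most extreme
  ev <- tibble(idx = c(pk, vl),
               type = rep(c("peak", "valley"), c(length(pk), length(vl)))) |>
    arrange(.data$idx)
  keep <- logical(nrow(ev))
  i <- 1L
  while (i <= nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1L] == ev$type[i]) j <- j + 1L
    run <- i:j
    vals <- xs[ev$idx[run]]
    best <- run[if (ev$type[i] == "peak") which.max(vals) else which.min(vals)]
    keep[best] <- TRUE
    i <- j + 1L
  }
  ev <- ev[keep, ]
  pk <- ev$idx[ev$type == "peak"]; vl <- ev$idx[ev$type == "valley"]
  if (length(pk) < 3 || length(vl) < 3) {
    abort("Too few breathing cycles after alternation filtering.",
          class = "rtstress_too_few_cycles")
  }
  # parabolic sub-sample refinement of extremum times on the smoothed signal
  refine <- function(idx) {
    off <- numeric(length(idx))
    ok <- idx > 1L & idx < n
    i <- idx[ok]
    den <- xs[i - 1L] - 2 * xs[i] + xs[i + 1L]
    o <- ifelse(abs(den) > 1e-12, 0.5 * (xs[i - 1L] - xs[i + 1L]) / den, 0)
    off[ok] <- pmin(1, pmax(-1, o))
    trace$time[idx] + off / fs
  }
  structure(list(peak_times = refine(pk), peak_values = x[pk],
                 valley_times = refine(vl), valley_values = x[vl]),
            class = "rt_extrema")
}

#' Respiratory irregularity
#'
#' The irregularity statistic is the mean of two standard deviations:
#' `amplitude_irr = (sd(peak values) + sd(valley values)) / 2` and
#' `phase_irr = (sd(peak-to-peak periods) + sd(valley-to-valley periods)) / 2`,
#' both with the sample (n-1) denominator. Amplitude irregularity is in
#' signal units; phase irregularity in seconds.
#'
#' @param extrema an `rt_extrema` from [detect_extrema()].
#' @return one-row tibble: `amplitude_irr`, `phase_irr`.
#' @export
resp_irregularity <- function(extrema) {
  if (length(extrema$peak_times) < 3 || length(extrema$valley_times) < 3) {
    abort("Irregularity needs at least 3 peaks and 3 valleys.",
          class = "rtstress_too_few_cycles")
  }
  tibble(
    amplitude_irr = (sd(extrema$peak_values) + sd(extrema$valley_values)) / 2,
    phase_irr = (sd(diff(extrema$peak_times)) + sd(diff(extrema$valley_times))) / 2
  )
}

#' Normalize stress scores to each patient's maximum
#'
#' Divides each case's score by the patient's maximum score, the scaling
#' used when plotting within-patient stress trajectories next to
#' irregularity trends. Patients whose scores are all zero get 0.
#'
#' @param cases case tibble with `patient_id` and `score`.
#' @return `cases` with an added `score_norm` column in \[0, 1\].
#' @export
normalize_scores_per_patient <- function(cases) {
  cases |>
    group_by(.data$patient_id) |>
    mutate(score_norm = if (max(.data$score) > 0) {
      .data$score / max(.data$score)
    } else {
      0
    }) |>
    ungroup()
}
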