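# PPG cleaning, phase segmentation, second-derivative beat detection and NN
# extraction.

#' Mask artifact spans in a trace
#'
#' Updates the validity mask without touching the samples. Three rules:
#' flatline (rolling 2 s variance below a floor), clipping (>= 3 consecutive
#' samples pinned at the trace extrema) and amplitude outliers (|robust z| >
#' 5 against a rolling 10 s median and the global MAD). Masked spans are
#' dilated by `dilate_s` on both sides so burst edges are covered.
#'
#' @param trace an [rt_trace()].
#' @param flat_window_s,flat_var_floor flatline window (s) and variance floor.
#' @param clip_run minimum run length at the extrema to call clipping.
#' @param z_window_s,z_max outlier window (s) and robust-z threshold.
#' @param dilate_s mask dilation (s) applied to detected spans.
#' @return the trace with an updated `valid` column; attribute
#'   `artifact_report` is a tibble of masked spans with reasons.
#' @export
remove_artifacts <- function(trace, flat_window_s = 2, flat_var_floor = 1e-8,
                             clip_run = 3, z_window_s = 10, z_max = 5,
                             dilate_s = 0.5) {
  fs <- trace_fs(trace)
  x <- trace$value
  n <- length(x)
  bad <- matrix(FALSE, n, 3, dimnames = list(NULL, c("flatline", "clipping", "outlier")))

  # flatline: variance over non-overlapping 2 s blocks below floor
  w <- max(2L, round(flat_window_s * fs))
  block <- ceiling(seq_len(n) / w)
  bvar <- tapply(x, block, var)
  bad[, "flatline"] <- bvar[block] < flat_var_floor

  # clipping: runs of >= clip_run samples at the extrema
  rng <- range(x)
  if (diff(rng) > 0) {
    at_edge <- x >= rng[2] - 1e-12 | x <= rng[1] + 1e-12
    r <- rle(at_edge)
    long <- r$values & r$lengths >= clip_run
    ends <- cumsum(r$lengths)
    for (i in which(long)) bad[(ends[i] - r$lengths[i] + 1L):ends[i], "clipping"] <- TRUE
  }

  # amplitude outlier: |x - rolling 10 s median| > 5 robust scale units.
  # The scale is the global IQR: wide enough that the periodic pulse
  # excursions of a clean PPG stay inside it, unlike the MAD of a
  # baseline-heavy signal.
  k <- round(z_window_s * fs)
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (n %% 2 == 1L) n else n - 1L)
  med <- if (k >= 3) stats::runmed(x, k, endrule = "median") else median(x)
  s <- stats::IQR(x)
  if (s > 0) bad[, "outlier"] <- abs(x - med) / s > z_max

  any_bad <- rowSums(bad) > 0
  if (any(any_bad)) {
    d <- round(dilate_s * fs)
    idx <- which(any_bad)
    grow <- unique(pmin(n, pmax(1L, rep(idx, each = 2 * d + 1) +
                                  rep(-d:d, times = length(idx)))))
    any_bad[grow] <- TRUE
  }

  valid <- trace$valid & !any_bad
  if (!any(valid)) {
    abort("Unusable segment: the entire trace is masked as artifact.",
          class = "rtstress_unusable_segment")
  }

  runs <- rle(!valid)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  report <- tibble(
    start_s = trace$time[starts[runs$values]],
    end_s = trace$time[ends[runs$values]],
    reason = vapply(which(runs$values), function(i) {
      span <- starts[i]:ends[i]
      hits <- colSums(bad[span, , drop = FALSE])
      if (all(hits == 0)) "pre-existing" else names(which.max(hits))
    }, character(1))
  )
  out <- trace_like(trace, valid = valid)
  attr(out, "artifact_report") <- report
  out
}

#' Cut the before/during analysis windows
#'
#' Each phase window is exactly 300 s starting 120 s after its phase mark:
#' the 2 min stabilization period absorbs the HR transient of walking in /
#' lying down, and the following 5 min is the analysis window. Windows are
#' half-open `[start, end)`; the validity mask is propagated.
#'
#' @param trace an [rt_trace()] with phase marks named `waiting_room` and
#'   `treatment`.
#' @param stabilization_s,window_s stabilization gap and window length (s).
#' @return named list of two [rt_trace()] windows: `before`, `during`.
#' @export
segment_phases <- function(trace, stabilization_s = 120, window_s = 300) {
  pm <- attr(trace, "phase_marks")
  need <- c("waiting_room", "treatment")
  if (is.null(pm) || !all(need %in% names(pm))) {
    abort("Both 'waiting_room' and 'treatment' phase marks are required.",
          class = "rtstress_bad_argument")
  }
  fs <- trace_fs(trace)
  end_of <- c(waiting_room = unname(pm["treatment"]),
              treatment = max(trace$time) + 1 / fs)
  out <- lapply(need, function(phase) {
    t0 <- unname(pm[phase]) + stabilization_s
    t1 <- t0 + window_s
    if (end_of[phase] < t1) {
      abort(sprintf(
        "Insufficient recording in the '%s' phase: need %g s after the mark, have %.1f s.",
        phase, stabilization_s + window_s, end_of[phase] - unname(pm[phase])),
        class = "rtstress_insufficient_recording")
    }
    sel <- trace$time >= t0 & trace$time < t1
    rt_trace(trace$value[sel], fs = fs, start = trace$time[sel][1],
             valid = trace$valid[sel], units = attr(trace, "units"),
             truth = attr(trace, "truth"))
  })
  names(out) <- c("before", "during")
  out
}

#' Detect heartbeats from the second derivative of the PPG
#'
#' Band-passes the signal (0.5-8 Hz), takes a smoothed (Savitzky-Golay)
#' second derivative, and finds local maxima of the negative curvature --
#' the sharp systolic upstroke is where the pulse wave bends hardest, so its
#' acceleration extremum marks the beat. Candidates must exceed an adaptive
#' prominence threshold (a fraction of the rolling upper-quantile curvature,
#' so absolute sensor gain does not matter) and respect a refractory period.
#' Beats falling in masked spans are discarded.
#'
#' @param trace an [rt_trace()].
#' @param band band-pass corner frequencies in Hz.
#' @param refractory_s minimum beat spacing (0.3 s caps HR at 200 bpm).
#' @param prominence fraction of the rolling 95th-percentile curvature a
#'   candidate must reach.
#' @param sg_width_s width of the Savitzky-Golay differentiation window (s).
#' @param min_beats fewer detections than this raises a warning condition.
#' @return numeric vector of beat times (s).
#' @export
detect_beats <- function(trace, band = c(0.5, 8), refractory_s = 0.3,
                         prominence = 0.3, sg_width_s = 0.13, min_beats = 30) {
  fs <- trace_fs(trace)
  if (fs < 50) abort("Beat detection requires fs >= 50 Hz.",
                     class = "rtstress_bad_argument")
  x <- trace$value
  n <- length(x)
  if (sd0(x) == 0) return(numeric(0))

  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))

  sg_n <- round(sg_width_s * fs)
  if (sg_n %% 2 == 0) sg_n <- sg_n + 1L
  sg_n <- max(sg_n, 5L)
  acc <- -signal::sgolayfilt(xf, p = 3, n = sg_n, m = 2) * fs^2

  is_peak <- c(FALSE, diff(acc[-n]) > 0 & diff(acc[-1]) <= 0, FALSE)
  cand <- which(is_peak & acc > 0)
  if (!length(cand)) return(numeric(0))

  # adaptive threshold: 95th percentile of positive curvature per 10 s block,
  # interpolated across blocks
  block_s <- 10
  blocks <- ceiling(trace$time / block_s)
  blocks <- blocks - min(blocks) + 1L
  q <- tapply(pmax(acc, 0), blocks, quantile, probs = 0.95)
  thr <- prominence * q[blocks]
  keep <- cand[acc[cand] >= thr[cand]]
  if (!length(keep)) return(numeric(0))

  # refractory: greedy acceptance by descending curvature
  ord <- keep[order(acc[keep], decreasing = TRUE)]
  t_cand <- trace$time[ord]
  accepted <- logical(0); accepted_t <- numeric(0)
  for (i in seq_along(ord)) {
    if (!length(accepted_t) || all(abs(accepted_t - t_cand[i]) >= refractory_s)) {
      accepted_t <- c(accepted_t, t_cand[i])
    }
  }
  beat_idx <- sort(match(accepted_t, trace$time))
  beat_idx <- beat_idx[trace$valid[beat_idx]]
  beats <- trace$time[beat_idx]

  window_min <- nrow(trace) / fs / 300 * min_beats
  if (length(beats) < window_min) {
    warn(sprintf("Too few beats: %d detected where >= %.0f expected.",
                 length(beats), window_min),
         class = "rtstress_too_few_beats")
  }
  beats
}

#' Convert beat times to a cleaned NN series
#'
#' Successive beat differences in ms, with two removal rules: intervals
#' outside \[300, 2000\] ms (missed or spurious beats), and intervals
#' deviating more than 20% from an 11-interval rolling median (ectopy /
#' detector slips). Removal counts are kept in the `removals` attribute.
#'
#' @param beat_times numeric beat times (s), strictly increasing.
#' @param range_ms acceptable interval range in ms.
#' @param median_window rolling-median width (intervals).
#' @param median_tol maximum relative deviation from the rolling median.
#' @param min_intervals minimum surviving intervals; fewer raises an
#'   "insufficient NN data" error. The default 0 keeps the constructor
#'   permissive; the HRV stage enforces its own >= 30 floor.
#' @return an [rt_nn()] with attribute `removals` = c(range, median).
#' @export
beats_to_nn <- function(beat_times, range_ms = c(300, 2000),
                        median_window = 11, median_tol = 0.2,
                        min_intervals = 0) {
  if (length(beat_times) < 2L) {
    abort("Need at least two beats.", class = "rtstress_too_few_beats")
  }
  nn <- diff(beat_times) * 1000
  ends <- beat_times[-1]

  in_range <- nn >= range_ms[1] & nn <= range_ms[2]
  n_range <- sum(!in_range)
  nn <- nn[in_range]; ends <- ends[in_range]

  n_med <- 0L
  if (length(nn) >= 3L) {
    k <- min(median_window, length(nn))
    if (k %% 2 == 0) k <- k - 1L
    med <- stats::runmed(nn, k, endrule = "median")
    ok <- abs(nn - med) / med <= median_tol
    n_med <- sum(!ok)
    nn <- nn[ok]; ends <- ends[ok]
  }

  if (length(nn) < max(1L, min_intervals)) {
    abort(sprintf("Insufficient NN data: %d intervals survive cleaning.",
                  length(nn)), class = "rtstress_insufficient_nn")
  }
  out <- rt_nn(c(ends[1] - nn[1] / 1000, ends), nn)
  attr(out, "removals") <- c(range = n_range, median = n_med)
  out
}
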