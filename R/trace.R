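#' Uniformly sampled sensor trace
#'
#' The common container for PPG and breathing signals: a tibble with columns
#' `time` (seconds from recording start), `value` (sensor units) and `valid`
#' (per-sample logical mask, `FALSE` inside artifact spans). Sampling rate,
#' phase marks (e.g. waiting-room entry and treatment-couch start) and any
#' generator ground truth ride along as attributes so the tibble itself stays
#' tidy.
#'
#' @param value numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param start time of the first sample in seconds.
#' @param valid logical vector of the same length as `value` (default all
#'   `TRUE`).
#' @param phase_marks named numeric vector of phase-start times in seconds,
#'   e.g. `c(waiting_room = 0, treatment = 650)`.
#' @param units character label for the value axis.
#' @param truth optional list of generator-side ground truth (beat times,
#'   breathing-cycle times) used only by tests.
#' @return a tibble of class `rt_trace`.
#' @export
rt_trace <- function(value, fs, start = 0, valid = NULL,
                     phase_marks = NULL, units = "a.u.", truth = NULL) {
  stopifnot_scalar_number(fs, "fs", lo = .Machine$double.eps)
  value <- as.numeric(value)
  n <- length(value)
  if (n == 0L) abort("An `rt_trace` needs at least one sample.",
                     class = "rtstress_bad_argument")
  valid <- valid %||% rep(TRUE, n)
  if (length(valid) != n) {
    abort("`valid` mask length must equal the number of samples.",
          class = "rtstress_bad_argument")
  }
  out <- tibble(
    time  = start + (seq_len(n) - 1) / fs,
    value = value,
    valid = as.logical(valid)
  )
  structure(out,
            fs = fs, phase_marks = phase_marks, units = units, truth = truth,
            class = c("rt_trace", class(out)))
}

#' @export
print.rt_trace <- function(x, ...) {
  cat(sprintf("<rt_trace> %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs"),
              100 * mean(x$valid)))
  if (!is.null(attr(x, "phase_marks"))) {
    pm <- attr(x, "phase_marks")
    cat("phase marks:", paste(names(pm), "=", pm, "s", collapse = ", "), "\n")
  }
  NextMethod()
}

trace_fs <- function(trace) attr(trace, "fs")

# Rebuild an rt_trace from a plain tibble plus the attributes of a template.
trace_like <- function(template, value = template$value,
                       valid = template$valid, start = template$time[1]) {
  rt_trace(value, fs = attr(template, "fs"), start = start, valid = valid,
           phase_marks = attr(template, "phase_marks"),
           units = attr(template, "units"), truth = attr(template, "truth"))
}

#' Write / read a trace as CSV plus JSON sidecar
#'
#' The on-disk exchange format for traces is a two-column CSV
#' (`time_s`, `value`) next to a JSON sidecar holding the sampling rate,
#' phase marks, the validity mask (as run-length spans of invalid samples)
#' and any generator ground truth. The same reader accepts plain two-column
#' exports with no sidecar, in which case the sampling rate is inferred from
#' the median time step.
#'
#' @param trace an [rt_trace()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   an [rt_trace()].
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time, value = trace$value)
  write.csv(df, path, row.names = FALSE)
  invalid <- !trace$valid
  runs <- rle(invalid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  side <- list(
    fs = attr(trace, "fs"),
    units = attr(trace, "units"),
    phase_marks = as.list(attr(trace, "phase_marks")),
    invalid_spans = data.frame(first = starts[runs$values],
                               last = ends[runs$values]),
    truth = attr(trace, "truth")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2) abort("Trace CSV needs (time, value) columns.",
                          class = "rtstress_bad_argument")
  names(df)[1:2] <- c("time_s", "value")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- side$fs
    pm <- unlist(side$phase_marks)
    valid <- rep(TRUE, nrow(df))
    spans <- as.data.frame(side$invalid_spans)
    if (nrow(spans)) {
      for (i in seq_len(nrow(spans))) {
        valid[spans$first[i]:spans$last[i]] <- FALSE
      }
    }
    truth <- side$truth
    units <- side$units %||% "a.u."
  } else {
    fs <- 1 / median(diff(df$time_s))
    pm <- NULL; valid <- rep(TRUE, nrow(df)); truth <- NULL; units <- "a.u."
  }
  rt_trace(df$value, fs = fs, start = df$time_s[1], valid = valid,
           phase_marks = pm, units = units,
           truth = if (length(truth)) truth else NULL)
}

#' Plot a sensor trace
#'
#' Line plot of the signal with invalid (masked) samples highlighted.
#'
#' @param object an [rt_trace()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rt_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::geom_point(
      data = dplyr::filter(df, !.data$valid),
      colour = "firebrick", size = 0.4
    ) +
    ggplot2::labs(x = "time (s)", y = attr(object, "units")) +
    ggplot2::theme_minimal()
}
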