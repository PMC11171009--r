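#' Normal-to-normal interval series
#'
#' One row per accepted NN interval: `beat_time` is the time (s) of the beat
#' that *ends* the interval, `nn_ms` the interval length in milliseconds.
#' The full vector of detected beat times (including the first beat, which
#' ends no interval) is kept as an attribute.
#'
#' @param beat_times strictly increasing beat times in seconds.
#' @param nn_ms interval lengths in ms; defaults to successive differences of
#'   `beat_times`. Must have one element per beat after the first.
#' @return a tibble of class `rt_nn` with columns `beat_time`, `nn_ms`.
#' @export
rt_nn <- function(beat_times, nn_ms = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L) {
    abort("An NN series needs at least two beats.", class = "rtstress_too_few_beats")
  }
  if (any(diff(beat_times) <= 0)) {
    abort("Beat times must be strictly increasing.", class = "rtstress_bad_argument")
  }
  nn_ms <- nn_ms %||% (diff(beat_times) * 1000)
  if (length(nn_ms) != length(beat_times) - 1L) {
    abort("Need one interval per beat after the first.", class = "rtstress_bad_argument")
  }
  out <- tibble(beat_time = beat_times[-1], nn_ms = as.numeric(nn_ms))
  structure(out, beat_times = beat_times,
            class = c("rt_nn", class(out)))
}

#' @export
print.rt_nn <- function(x, ...) {
  cat(sprintf("<rt_nn> %d NN intervals over %.1f s (mean %.0f ms)\n",
              nrow(x), diff(range(attr(x, "beat_times"))), mean(x$nn_ms)))
  NextMethod()
}

#' Write / read an NN series as CSV
#'
#' Two columns: `beat_time_s` (interval-ending beat) and `nn_ms`.
#'
#' @param nn an [rt_nn()].
#' @param path CSV path.
#' @return `write_nn()` returns `path` invisibly; `read_nn()` an [rt_nn()].
#' @export
write_nn <- function(nn, path) {
  write.csv(data.frame(beat_time_s = nn$beat_time, nn_ms = nn$nn_ms),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nn
#' @export
read_nn <- function(path) {
  df <- read.csv(path)
  first_beat <- df$beat_time_s[1] - df$nn_ms[1] / 1000
  rt_nn(c(first_beat, df$beat_time_s), df$nn_ms)
}
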