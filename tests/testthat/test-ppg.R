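# Artifact masking, phase segmentation, beat detection, NN cleaning.

test_that("clean traces pass artifact screening untouched", {
  nn <- generate_nn_series(tachogram_spec(70, 35, 1.2, 120), seed = 6)
  ppg <- synthesize_ppg(nn, fs = 100, noise_sd = 0.05, seed = 6)
  cleaned <- remove_artifacts(ppg)
  expect_true(all(cleaned$valid))
  expect_identical(cleaned$value, ppg$value)
  expect_equal(nrow(attr(cleaned, "artifact_report")), 0)
})

test_that("flatline traces are fully masked and flagged unusable", {
  expect_error(remove_artifacts(rt_trace(rep(1, 1000), fs = 100)),
               class = "rtstress_unusable_segment")
})

test_that("clipped spans are masked with the clipping reason", {
  nn <- generate_nn_series(tachogram_spec(70, 30, 1.2, 60), seed = 2)
  ppg <- synthesize_ppg(nn, fs = 100, noise_sd = 0.03, seed = 2)
  x <- ppg$value
  x[2000:2200] <- max(x) + 0.5   # saturated run
  tr <- rt_trace(x, fs = 100)
  cleaned <- remove_artifacts(tr)
  expect_true(all(!cleaned$valid[2000:2200]))
  expect_true("clipping" %in% attr(cleaned, "artifact_report")$reason)
})

test_that("phase windows are 300 s starting 120 s after each mark, half-open", {
  nn <- generate_nn_series(tachogram_spec(70, 35, 1.5, 1300), seed = 9)
  tr <- synthesize_ppg(nn, fs = 100, noise_sd = 0.04,
                       phase_marks = c(waiting_room = 0, treatment = 650),
                       seed = 9)
  ph <- segment_phases(tr)
  expect_equal(min(ph$before$time), 120)
  expect_lt(max(ph$before$time), 420)
  expect_equal(nrow(ph$before), 300 * 100)
  expect_equal(min(ph$during$time), 770)
  expect_equal(nrow(ph$during), 300 * 100)
})

test_that("short phases raise an insufficient-recording error naming the phase", {
  nn <- generate_nn_series(tachogram_spec(70, 35, 1.5, 500), seed = 2)
  tr <- synthesize_ppg(nn, fs = 100, noise_sd = 0.04,
                       phase_marks = c(waiting_room = 0, treatment = 380),
                       seed = 2)
  expect_error(segment_phases(tr), regexp = "waiting_room",
               class = "rtstress_insufficient_recording")
})

test_that("masked spans propagate into the cut windows", {
  nn <- generate_nn_series(tachogram_spec(70, 35, 1.5, 1300), seed = 4)
  tr <- synthesize_ppg(nn, fs = 100, noise_sd = 0.04,
                       phase_marks = c(waiting_room = 0, treatment = 650),
                       seed = 4)
  bad <- tr$time >= 200 & tr$time < 205
  tr2 <- rt_trace(tr$value, fs = 100, valid = !bad,
                  phase_marks = attr(tr, "phase_marks"))
  ph <- segment_phases(tr2)
  inside <- ph$before$time >= 200 & ph$before$time < 205
  expect_true(all(!ph$before$valid[inside]))
  expect_true(all(ph$before$valid[!inside]))
})

test_that("beat detector recovers clean synthetic beats and ignores masked spans", {
  nn <- generate_nn_series(tachogram_spec(60, 40, 1.0, 300), seed = 13)
  ppg <- synthesize_ppg(nn, fs = 100, noise_sd = 0.05, seed = 13)
  truth <- attr(ppg, "truth")$beat_times
  beats <- detect_beats(ppg)
  recall <- mean(vapply(truth, function(b) min(abs(beats - b)) <= 0.02, logical(1)))
  precision <- mean(vapply(beats, function(b) min(abs(truth - b)) <= 0.02, logical(1)))
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)

  masked <- rt_trace(ppg$value, fs = 100,
                     valid = !(ppg$time >= 50 & ppg$time < 60))
  beats_m <- detect_beats(masked)
  expect_false(any(beats_m >= 50 & beats_m < 60))
})

test_that("detector recall degrades monotonically with noise", {
  nn <- generate_nn_series(tachogram_spec(60, 40, 1.0, 120), seed = 17)
  recalls <- vapply(c(0.05, 0.6, 1.5), function(ns) {
    ppg <- synthesize_ppg(nn, fs = 100, noise_sd = ns, seed = 17)
    truth <- attr(ppg, "truth")$beat_times
    beats <- suppressWarnings(detect_beats(ppg))
    if (!length(beats)) return(0)
    mean(vapply(truth, function(b) min(abs(beats - b)) <= 0.02, logical(1)))
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0.02))  # non-increasing up to tiny jitter
  expect_lt(recalls[3], recalls[1])
})

test_that("flat input yields no beats; close pulse pairs obey the refractory period", {
  expect_length(detect_beats(rt_trace(rep(0.3, 6000), fs = 100)), 0)
  onsets <- c(seq(1, 9, by = 1), 9.2, seq(10.5, 29, by = 1))
  tr <- synthesize_ppg(onsets, fs = 100, noise_sd = 0, seed = 1)
  beats <- suppressWarnings(detect_beats(tr))
  pair <- beats[beats >= 9.05 & beats <= 9.55]   # truth peaks at 9.2 and 9.4
  expect_length(pair, 1)
})

test_that("beats_to_nn computes intervals and applies both removal rules", {
  nn <- beats_to_nn(0:10)
  expect_equal(nn$nn_ms, rep(1000, 10))

  spur <- beats_to_nn(c(0:5, 5.2, 6:10))
  expect_false(any(spur$nn_ms < 300))
  expect_equal(unname(attr(spur, "removals")["range"]), 1)

  missed <- beats_to_nn(c(0:5, 7.2, 8.2:10.2))
  expect_false(any(missed$nn_ms > 2000))
  expect_gte(sum(attr(missed, "removals")), 1)

  expect_error(beats_to_nn(c(0, 1), min_intervals = 30),
               class = "rtstress_insufficient_nn")
  expect_error(beats_to_nn(1), class = "rtstress_too_few_beats")
})

test_that("beats_to_nn is idempotent on an already-clean series", {
  nn <- generate_nn_series(tachogram_spec(65, 30, 1.0, 300), seed = 5)
  once <- beats_to_nn(attr(nn, "beat_times"))
  expect_equal(sum(attr(once, "removals")), 0)
  twice <- beats_to_nn(attr(once, "beat_times"))
  expect_equal(twice$nn_ms, once$nn_ms, tolerance = 1e-10)
})

test_that("full signal chain recovers the generator's HRV targets", {
  nn <- generate_nn_series(tachogram_spec(60, 40, 1.0, 300), seed = 19)
  ppg <- synthesize_ppg(nn, fs = 100, noise_sd = 0.05, seed = 19)
  cleaned <- remove_artifacts(ppg)
  beats <- detect_beats(cleaned)
  feats <- compute_hrv_features(beats_to_nn(beats))
  expect_lt(abs(feats$hr - 60) / 60, 0.03)
  expect_lt(abs(feats$sdnn - 40) / 40, 0.15)
})
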