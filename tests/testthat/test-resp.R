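# Breathing extrema, the irregularity statistic, per-patient normalization,
# and the clustered association model.

test_that("a 4 s sinusoid yields 15 peaks and valleys at the true phase", {
  tt <- seq(0, 60 - 1 / 25, by = 1 / 25)
  ex <- detect_extrema(rt_trace(sin(2 * pi * tt / 4), fs = 25))
  expect_length(ex$peak_times, 15)
  expect_length(ex$valley_times, 15)
  expect_lt(max(abs(ex$peak_times - (seq_len(15) * 4 - 3))), 0.1)
  expect_lt(max(abs(ex$valley_times - (seq_len(15) * 4 - 1))), 0.1)
})

test_that("monotone ramps and too-short traces are rejected", {
  tt <- seq(0, 60 - 1 / 25, by = 1 / 25)
  expect_error(detect_extrema(rt_trace(tt, fs = 25)),
               class = "rtstress_too_few_cycles")
  expect_error(detect_extrema(rt_trace(sin(tt[1:200]), fs = 25)),
               class = "rtstress_bad_argument")
})

test_that("noise notches produce one kept extremum per cycle (alternation)", {
  tt <- seq(0, 60 - 1 / 25, by = 1 / 25)
  x <- sin(2 * pi * tt / 4)
  # carve a small notch near one peak -> two same-sign candidates
  near <- abs(tt - 9) < 0.2
  x[near] <- x[near] - 0.15
  ex <- detect_extrema(rt_trace(x, fs = 25), smooth_s = 0.2)
  expect_length(ex$peak_times, 15)
  expect_true(all(diff(sort(c(ex$peak_times, ex$valley_times))) > 0))
  # strict alternation
  ty <- rep(c("p", "v"), c(15, length(ex$valley_times)))
  ord <- order(c(ex$peak_times, ex$valley_times))
  expect_true(all(ty[ord][-1] != ty[ord][-length(ty)]))
})

test_that("the irregularity statistic equals its closed form on fixed extrema", {
  ex <- structure(list(peak_times = c(0, 4, 8), peak_values = c(10, 12, 14),
                       valley_times = c(2, 6, 10), valley_values = c(0, 2, 4)),
                  class = "rt_extrema")
  irr <- resp_irregularity(ex)
  expect_equal(irr$amplitude_irr, 2)
  expect_equal(irr$phase_irr, 0)
  ex$peak_times <- c(0, 3, 8)   # periods 3 and 5: sd = sqrt(2)
  irr2 <- resp_irregularity(ex)
  expect_equal(irr2$phase_irr, sqrt(2) / 2)
  ex$valley_times <- c(2, 6)
  expect_error(resp_irregularity(ex), class = "rtstress_too_few_cycles")
})

test_that("irregularity is shift-invariant and equivariant under scaling", {
  tr <- generate_resp_trace(period_sd = 0.3, amp_sd = 0.2, duration = 120, seed = 5)
  i1 <- resp_irregularity(detect_extrema(tr))
  i_shift <- resp_irregularity(detect_extrema(rt_trace(tr$value + 10, fs = 25)))
  expect_equal(i_shift$amplitude_irr, i1$amplitude_irr, tolerance = 1e-9)
  expect_equal(i_shift$phase_irr, i1$phase_irr, tolerance = 1e-9)
  i_scale <- resp_irregularity(detect_extrema(rt_trace(tr$value * 3, fs = 25)))
  expect_equal(i_scale$amplitude_irr, 3 * i1$amplitude_irr, tolerance = 1e-6)
  expect_equal(i_scale$phase_irr, i1$phase_irr, tolerance = 1e-6)
})

test_that("per-patient score normalization follows the max-score convention", {
  cases <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c"),
    score = c(42.86, 85.71, 0, 0, 57.14)
  )
  out <- normalize_scores_per_patient(cases)
  expect_equal(out$score_norm, c(42.86 / 85.71, 1, 0, 0, 1), tolerance = 1e-9)
})

test_that("the GEE reduces to OLS + cluster-robust errors under independence", {
  skip_if_not_installed("sandwich")
  set.seed(42)
  np <- 30
  df <- data.frame(id = rep(seq_len(np), each = 3))
  u <- rnorm(np, 0, 2)
  df$x <- runif(np * 3, 0, 10)
  df$y <- 1 + 0.5 * df$x + u[df$id] + rnorm(np * 3)
  g0 <- gee_gaussian(y ~ x, df, id = df$id, corstr = "independence")
  f <- lm(y ~ x, df)
  expect_equal(unname(g0$coefficients), unname(coef(f)), tolerance = 1e-10)
  v <- sandwich::vcovCL(f, cluster = df$id, type = "HC0", cadjust = TRUE)
  expect_equal(unname(g0$vcov), unname(v), tolerance = 1e-8)
})

test_that("exchangeable GEE coefficients match compound-symmetry GLS", {
  skip_if_not_installed("nlme")
  set.seed(43)
  np <- 25
  df <- data.frame(id = rep(seq_len(np), each = 4))
  u <- rnorm(np, 0, 1.5)
  df$x <- runif(np * 4)
  df$y <- 2 - 1.2 * df$x + u[df$id] + rnorm(np * 4)
  g <- gee_gaussian(y ~ x, df, id = df$id)
  gl <- nlme::gls(y ~ x, df, correlation = nlme::corCompSymm(form = ~ 1 | id),
                  method = "ML")
  expect_equal(unname(g$coefficients), unname(coef(gl)), tolerance = 0.05)
  td <- tidy(g)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("the association model recovers the generating slope without bias", {
  betas <- vapply(1:30, function(r) {
    co <- generate_cohort(cohort_config(n_patients = 40, days_per_patient = c(3, 3),
                                        resp_slope = 0.3, seed = 5000 + r))
    associate_irregularity(co, "score10", "phase_irr")$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.3), 3 * sd(betas) / sqrt(30))
})

test_that("confidence intervals widen with the residual noise level", {
  width_at <- function(noise) {
    mean(vapply(1:20, function(r) {
      co <- generate_cohort(cohort_config(n_patients = 40, days_per_patient = c(3, 3),
                                          resp_slope = 0.3, noise_sd = noise,
                                          seed = 7000 + r))
      a <- associate_irregularity(co, "score10", "phase_irr")
      a$ucl - a$lcl
    }, numeric(1)))
  }
  expect_lt(width_at(2.5), width_at(5))
})

test_that("a single cluster falls back to robust OLS with a warning", {
  co <- generate_cohort(cohort_config(n_patients = 1, days_per_patient = c(5, 5),
                                      seed = 2))
  expect_warning(a <- associate_irregularity(co, "score10", "phase_irr"),
                 class = "rtstress_single_cluster")
  expect_true(is.finite(a$beta))
  expect_equal(a$n_patients, 1)
})

test_that("binary and score predictors both produce ordered intervals", {
  co <- generate_cohort(cohort_config(seed = 9))
  tab <- irregularity_table(co)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$lcl <= tab$beta & tab$beta <= tab$ucl))
  expect_setequal(unique(tab$response), c("phase_irr", "amp_irr"))
})
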