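# Synthetic cohort generator: case tables with before/during HRV features,
# directional stress structure, and breathing irregularity coupled to the
# latent stress score through patient-level random effects.

#' Cohort generator configuration
#'
#' Defaults describe the emulated study population: 41 lung-cancer patients
#' (about two thirds male, ages 47-80) measured on 1-5 treatment days each;
#' each of the seven HRV features shifts in its stressful direction with
#' probability `p_stress` (0.5 by default, matching a mean of ~3.5 stressful
#' shifts out of 7); phase irregularity rises by `resp_slope` units per 10
#' stress-score points around an intercept of ~8.6 with patient-level and
#' residual noise chosen to give a mean near 10 and a 3-30 spread.
#'
#' @param n_patients number of patients.
#' @param days_per_patient integer range `c(min, max)` of measurement days
#'   sampled uniformly per patient.
#' @param sex_ratio fraction of male patients in \[0, 1\].
#' @param age_range `c(min, max)` ages in years.
#' @param p_stress probability, per feature, that the during-treatment value
#'   moves in the stressful direction; either one number or a length-7
#'   vector in Table-order (hr, sdnn, rmssd, pnn50, hf, lf_hf, tp).
#' @param p_stress_sex_gap added to male and subtracted from female
#'   `p_stress` in equal halves (for sex-difference power studies); 0 keeps
#'   both sexes identical.
#' @param shift_magnitude relative size of a feature shift (fraction of the
#'   before-treatment value).
#' @param resp_intercept baseline phase irregularity (trace units).
#' @param resp_slope true increase in phase irregularity per 10 stress-score
#'   points.
#' @param patient_sd SD of the patient-level random intercept for
#'   irregularity.
#' @param noise_sd residual irregularity noise SD.
#' @param amp_scale amplitude irregularity is generated as `amp_scale` times
#'   the phase linear predictor plus its own noise, mirroring the much
#'   smaller amplitude effect.
#' @param seed integer seed; fully determines the cohort.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 41, days_per_patient = c(1, 5),
                          sex_ratio = 0.6585, age_range = c(47, 80),
                          p_stress = 0.5, p_stress_sex_gap = 0,
                          shift_magnitude = 0.15,
                          resp_intercept = 8.6, resp_slope = 0.286,
                          patient_sd = 4, noise_sd = 2.5,
                          amp_scale = 0.014, seed = 1) {
  stopifnot_scalar_number(n_patients, "n_patients", 1)
  stopifnot_scalar_number(sex_ratio, "sex_ratio", 0, 1)
  if (!length(p_stress) %in% c(1L, 7L) || any(p_stress < 0 | p_stress > 1)) {
    abort("`p_stress` must be 1 or 7 probabilities in [0, 1].",
          class = "rtstress_bad_argument")
  }
  if (length(days_per_patient) != 2L || days_per_patient[1] < 1 ||
      days_per_patient[2] < days_per_patient[1]) {
    abort("`days_per_patient` must be an increasing positive range.",
          class = "rtstress_bad_argument")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# Plausible resting-state feature draws for one case (before treatment).
draw_before_features <- function(n) {
  hf <- exp(rnorm(n, log(300), 0.5))
  lf <- exp(rnorm(n, log(400), 0.5))
  vlf <- exp(rnorm(n, log(500), 0.5))
  tibble(
    hr    = rnorm(n, 72, 8),
    sdnn  = exp(rnorm(n, log(35), 0.3)),
    rmssd = exp(rnorm(n, log(28), 0.35)),
    pnn50 = pmin(95, exp(rnorm(n, log(8), 0.6))),
    hf    = hf,
    lf_hf = lf / hf,
    tp    = hf + lf + vlf
  )
}

#' Generate a synthetic cohort of patient-day cases
#'
#' Draws patients (sex, age, number of treatment days), before-treatment HRV
#' features, then moves each feature in its stressful direction with
#' probability `p_stress` (and in the opposite direction otherwise) by a
#' relative amount around `shift_magnitude`. The stress labels, quantized
#' score, and binary call are computed through the package's own scoring
#' functions, and phase/amplitude breathing irregularity is generated as a
#' linear function of the true score with patient random effects.
#'
#' @param config a [cohort_config()].
#' @param with_traces if `TRUE`, attach list-columns `before_nn` and
#'   `during_nn` holding synthetic NN series consistent with each case's HR,
#'   SDNN and LF/HF (slower; off by default).
#' @return a tibble with one row per case: `patient_id`, `sex`, `age`,
#'   `day`, `before_*` and `during_*` feature columns, label columns
#'   `l_hr` ... `l_tp`, `score`, `stressed`, `phase_irr`, `amp_irr`.
#' @export
generate_cohort <- function(config = cohort_config(), with_traces = FALSE) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  feats <- stress_feature_names()
  with_local_seed(config$seed, {
    np <- config$n_patients
    patients <- tibble(
      patient_id = sprintf("P%03d", seq_len(np)),
      sex = ifelse(runif(np) < config$sex_ratio, "M", "F"),
      age = round(runif(np, config$age_range[1], config$age_range[2])),
      n_days = {
        day_choices <- seq(config$days_per_patient[1], config$days_per_patient[2])
        day_choices[sample.int(length(day_choices), np, replace = TRUE)]
      },
      patient_effect = rnorm(np, 0, config$patient_sd)
    )
    cases <- tidyr::uncount(patients, weights = .data$n_days, .remove = FALSE) |>
      group_by(.data$patient_id) |>
      mutate(day = row_number()) |>
      ungroup() |>
      select(-"n_days")
    n <- nrow(cases)

    before <- draw_before_features(n)
    p <- if (length(config$p_stress) == 1L) rep(config$p_stress, 7) else config$p_stress
    gap <- config$p_stress_sex_gap / 2
    dirs <- stress_directions()$direction    # "increase"/"decrease" per feature
    during <- before
    for (j in seq_along(feats)) {
      pj <- pmin(1, pmax(0, p[j] + ifelse(cases$sex == "M", gap, -gap)))
      toward_stress <- runif(n) < pj
      mag <- config$shift_magnitude * runif(n, 0.5, 1.5)
      sgn <- ifelse(dirs[j] == "increase", 1, -1) * ifelse(toward_stress, 1, -1)
      during[[feats[j]]] <- before[[feats[j]]] * (1 + sgn * mag)
    }
    during$pnn50 <- pmin(100, during$pnn50)

    before_w <- rlang::set_names(before, paste0("before_", feats))
    during_w <- rlang::set_names(during, paste0("during_", feats))
    out <- bind_cols(select(cases, "patient_id", "sex", "age", "day"),
                     before_w, during_w)
    out <- assess_cases(out)

    lin <- config$resp_intercept + config$resp_slope * out$score / 10 +
      cases$patient_effect
    out$phase_irr <- pmax(0.1, lin + rnorm(n, 0, config$noise_sd))
    out$amp_irr <- pmax(0.01, config$amp_scale *
                          (lin + rnorm(n, 0, config$noise_sd)))

    if (with_traces) {
      out$before_nn <- purrr::pmap(
        list(out$before_hr, out$before_sdnn, out$before_lf_hf, seq_len(n)),
        function(hr, sdnn, lfhf, i) {
          generate_nn_series(tachogram_spec(hr, sdnn, lfhf, 300),
                             seed = child_seed(config$seed, 2L * i))
        })
      out$during_nn <- purrr::pmap(
        list(out$during_hr, out$during_sdnn, out$during_lf_hf, seq_len(n)),
        function(hr, sdnn, lfhf, i) {
          generate_nn_series(tachogram_spec(hr, sdnn, lfhf, 300),
                             seed = child_seed(config$seed, 2L * i + 1L))
        })
    }
    attr(out, "config") <- config
    out
  })
}

#' Write a cohort case table (CSV) with its config echo (JSON)
#'
#' @param cases a cohort tibble from [generate_cohort()].
#' @param path CSV path; the config echo goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cases, path) {
  flat <- dplyr::select(cases, -dplyr::any_of(c("before_nn", "during_nn")))
  write.csv(as.data.frame(flat), path, row.names = FALSE)
  cfg <- attr(cases, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as_tibble(read.csv(path))
}
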