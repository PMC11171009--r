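# Cohort-level reporting: score-bin distribution, day/sex comparisons,
# composition arithmetic, and the end-to-end pipeline driver.

#' Stress-score distribution summary
#'
#' Frequency table of the occupied score bins (counts and percentages of all
#' cases, percentages rounded half-up to two decimals), plus stressed-case
#' counts by treatment day and by sex.
#'
#' @param cases assessed case tibble (needs `score`; `day`/`sex` used when
#'   present).
#' @return list of class `rt_distribution`: `bins`, `by_day`, `by_sex`,
#'   `n_cases`, `pct_nonzero`, `pct_stressed`.
#' @export
summarize_distribution <- function(cases) {
  if (nrow(cases) < 1) abort("Need at least one case.", class = "rtstress_bad_argument")
  n <- nrow(cases)
  bins <- cases |>
    dplyr::count(score = .data$score, name = "n") |>
    arrange(.data$score) |>
    mutate(pct = round_half_up(100 * .data$n / !!n, 2))
  by_day <- if ("day" %in% names(cases)) {
    cases |>
      group_by(day = .data$day) |>
      summarise(n_cases = n(), n_stressed = sum(.data$score > 50),
                mean_score = mean(.data$score), .groups = "drop")
  }
  by_sex <- if ("sex" %in% names(cases)) {
    cases |>
      group_by(sex = .data$sex) |>
      summarise(n_cases = n(), n_stressed = sum(.data$score > 50),
                mean_score = mean(.data$score), .groups = "drop")
  }
  structure(list(
    bins = bins, by_day = by_day, by_sex = by_sex, n_cases = n,
    pct_nonzero = round_half_up(100 * mean(cases$score > 0), 2),
    pct_stressed = round_half_up(100 * mean(cases$score > 50), 2)
  ), class = "rt_distribution")
}

#' @export
print.rt_distribution <- function(x, ...) {
  cat(sprintf("<rt_distribution> %d cases: %.2f%% with any stress shift, %.2f%% above the 50%% threshold\n",
              x$n_cases, x$pct_nonzero, x$pct_stressed))
  print(x$bins)
  invisible(x)
}

#' Plot the stress-score distribution
#'
#' @param object an `rt_distribution`.
#' @param ... unused.
#' @return a ggplot bar chart of bin percentages.
#' @export
autoplot.rt_distribution <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = factor(.data$score), y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "stress score (%)", y = "cases (%)") +
    ggplot2::theme_minimal()
}

#' Day-by-sex stress-score comparison
#'
#' Per-day male/female score means and SDs with a two-sided Mann-Whitney U
#' test per day, and a Friedman trend test per sex across days (computed on
#' patients observed on every requested day). Degenerate cells (an empty
#' group, or no score variation for the trend test) are reported as `NA`
#' with a note rather than an error.
#'
#' @param cases assessed case tibble with `sex`, `day`, `score`,
#'   `patient_id`.
#' @param days which treatment days to compare (default 1-4, where case
#'   counts remain reasonable).
#' @return list of class `rt_day_sex`: `by_day` tibble (day, per-sex mean,
#'   sd, n, `p_value` from the Mann-Whitney test) and `trend` tibble
#'   (per-sex Friedman chi-square and p, plus a note).
#' @export
day_sex_comparisons <- function(cases, days = 1:4) {
  df <- dplyr::filter(cases, .data$day %in% days)
  if (nrow(df) < 4) abort("Need at least 2 groups with 2 cases.",
                          class = "rtstress_bad_argument")
  by_day <- purrr::map(sort(unique(df$day)), function(d) {
    m <- df$score[df$day == d & df$sex == "M"]
    f <- df$score[df$day == d & df$sex == "F"]
    p <- if (length(m) >= 2 && length(f) >= 2) {
      suppressWarnings(wilcox.test(m, f, exact = NULL)$p.value)
    } else NA_real_
    tibble(day = d,
           n_male = length(m), mean_male = mean(m), sd_male = sd0(m),
           n_female = length(f), mean_female = mean(f), sd_female = sd0(f),
           p_value = p)
  }) |> bind_rows()

  trend <- purrr::map(c("M", "F"), function(s) {
    wide <- df |>
      dplyr::filter(.data$sex == s) |>
      select("patient_id", "day", "score") |>
      tidyr::pivot_wider(names_from = "day", values_from = "score",
                         values_fn = mean) |>
      dplyr::filter(complete.cases(dplyr::pick(dplyr::everything())))
    m <- as.matrix(wide[-1])
    if (nrow(m) < 2 || ncol(m) < 2) {
      return(tibble(sex = s, statistic = NA_real_, p_value = NA_real_,
                    note = "too few complete patients"))
    }
    if (sd0(as.vector(m)) == 0) {
      return(tibble(sex = s, statistic = NA_real_, p_value = NA_real_,
                    note = "no score variation"))
    }
    ft <- friedman.test(m)
    tibble(sex = s, statistic = unname(ft$statistic),
           p_value = ft$p.value, note = NA_character_)
  }) |> bind_rows()

  structure(list(by_day = by_day, trend = trend), class = "rt_day_sex")
}

#' @export
print.rt_day_sex <- function(x, ...) {
  print(x$by_day); cat("trend (Friedman):\n"); print(x$trend)
  invisible(x)
}

#' Cohort composition summary
#'
#' Patient-level counts and percentages by sex with age summaries -- the
#' characteristics-table arithmetic (percentages rounded half-up to two
#' decimals).
#'
#' @param patients tibble with one row per patient: `sex`, optionally `age`.
#' @return tibble with rows per sex and overall: n, pct, and (when ages are
#'   available) mean/min/max age.
#' @export
cohort_composition <- function(patients) {
  n <- nrow(patients)
  has_age <- "age" %in% names(patients)
  overall <- tibble(group = "all", n = n, pct = 100)
  by_sex <- patients |>
    group_by(group = .data$sex) |>
    summarise(n = n(), pct = round_half_up(100 * n() / !!n, 2),
              .groups = "drop")
  if (has_age) {
    overall <- mutate(overall, mean_age = mean(patients$age),
                      min_age = min(patients$age), max_age = max(patients$age))
    ages <- patients |>
      group_by(group = .data$sex) |>
      summarise(mean_age = mean(.data$age), min_age = min(.data$age),
                max_age = max(.data$age), .groups = "drop")
    by_sex <- left_join(by_sex, ages, by = "group")
  }
  bind_rows(overall, by_sex)
}

#' Enrollment response rate
#'
#' Share of approached patients who consented, as a percentage.
#'
#' @param approached,consented counts.
#' @param digits decimals for the reported percentage (enrollment rates are
#'   conventionally reported as whole percents).
#' @return percentage, rounded half-up.
#' @export
enrollment_rate <- function(approached, consented, digits = 0) {
  stopifnot_scalar_number(approached, "approached", 1)
  stopifnot_scalar_number(consented, "consented", 0, approached)
  round_half_up(100 * consented / approached, digits)
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a cohort, summarizes the score distribution, runs the day/sex
#' comparison, cross-validates the requested predictor(s), and fits the
#' irregularity associations. With `out_dir` set, writes the case table and
#' every report as CSV (plus a JSON config echo); outputs are byte-identical
#' across reruns with the same config.
#'
#' @param config a [cohort_config()].
#' @param models model families to cross-validate (default `"forest"`).
#' @param dataset_types dataset variants to evaluate (default 1 and 8).
#' @param k cross-validation folds.
#' @param grouped patient-grouped folds (see [crossvalidate()]).
#' @param out_dir optional output directory.
#' @return list of class `rt_pipeline`: `cases`, `distribution`, `day_sex`,
#'   `cv` (tibble over models x types), `association`, `log`.
#' @export
run_pipeline <- function(config = cohort_config(), models = "forest",
                         dataset_types = c(1, 8), k = 10, grouped = TRUE,
                         out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  cases <- generate_cohort(config)
  note("generated %d cases from %d patients", nrow(cases), config$n_patients)

  dist <- summarize_distribution(cases)
  day_sex <- tryCatch(day_sex_comparisons(cases),
                      error = function(e) {
                        note("day/sex comparison skipped: %s", conditionMessage(e))
                        NULL
                      })

  grid <- tidyr::expand_grid(model = models, dataset_type = dataset_types)
  cv <- purrr::pmap(grid, function(model, dataset_type) {
    ds <- build_dataset(cases, dataset_type)
    glance(crossvalidate(ds, model, k = min(k, nrow(ds$inputs)),
                         seed = child_seed(config$seed, dataset_type),
                         grouped = grouped))
  }) |> bind_rows()
  note("cross-validated %d model x dataset combinations", nrow(cv))

  assoc <- irregularity_table(cases)
  note("fitted %d irregularity associations over %d cases", nrow(assoc),
       nrow(cases))

  out <- structure(list(cases = cases, distribution = dist,
                        day_sex = day_sex, cv = cv, association = assoc,
                        log = log),
                   class = "rt_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cases, file.path(out_dir, "cases.csv"))
    write.csv(as.data.frame(dist$bins), file.path(out_dir, "score_bins.csv"),
              row.names = FALSE)
    if (!is.null(day_sex)) {
      write.csv(as.data.frame(day_sex$by_day),
                file.path(out_dir, "day_sex.csv"), row.names = FALSE)
    }
    write.csv(as.data.frame(cv), file.path(out_dir, "cv_metrics.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(assoc), file.path(out_dir, "association.csv"),
              row.names = FALSE)
    writeLines(log, file.path(out_dir, "pipeline_log.txt"))
  }
  out
}

#' @export
print.rt_pipeline <- function(x, ...) {
  cat("<rt_pipeline>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Plot irregularity against stress score
#'
#' Scatter of case-level irregularity vs stress score with the marginal
#' regression line implied by the association fit.
#'
#' @param object an `rt_assoc` row (from [associate_irregularity()] with
#'   `predictor = "score10"`).
#' @param cases the case tibble the association was fitted on.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rt_assoc <- function(object, cases, ...) {
  resp <- object$response[1]
  ggplot2::ggplot(cases, ggplot2::aes(x = .data$score, y = .data[[resp]])) +
    ggplot2::geom_point(alpha = 0.5, colour = "grey30") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "stress score (%)", y = resp,
                  subtitle = sprintf("beta = %.3f per 10%% [%.3f, %.3f]",
                                     object$beta[1], object$lcl[1],
                                     object$ucl[1])) +
    ggplot2::theme_minimal()
}
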