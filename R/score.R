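# Directional stress scoring: seven feature-change labels, the quantized
# score (multiples of 100/7), and the binary stress call.

#' Canonical feature order
#'
#' The seven stress-related HRV features in the order used throughout the
#' package: `hr`, `sdnn`, `rmssd`, `pnn50`, `hf`, `lf_hf`, `tp`.
#'
#' @return character vector of length 7.
#' @export
stress_feature_names <- function() {
  c("hr", "sdnn", "rmssd", "pnn50", "hf", "lf_hf", "tp")
}

#' Stressful-direction table
#'
#' Under acute stress, sympathetic activation typically raises heart rate and
#' the LF/HF balance while suppressing overall variability: SDNN, RMSSD,
#' pNN50, HF power and total power all fall. A feature "moves stressfully"
#' when its during-treatment value moves in this direction relative to the
#' waiting-room value.
#'
#' @return a tibble with columns `feature` and `direction`
#'   (`"increase"`/`"decrease"`).
#' @export
stress_directions <- function() {
  tibble(
    feature = stress_feature_names(),
    direction = c("increase", "decrease", "decrease", "decrease",
                  "decrease", "increase", "decrease")
  )
}

# Coerce a features argument (one-row tibble / named list / named vector)
# into a named numeric vector over the canonical seven features.
as_feature_vector <- function(x, arg = "features") {
  if (is_tibble(x) || is.data.frame(x)) {
    if (nrow(x) != 1L) abort(sprintf("`%s` must be a single case.", arg),
                             class = "rtstress_bad_argument")
    x <- as.list(x)
  }
  x <- unlist(x)
  missing <- setdiff(stress_feature_names(), names(x))
  if (length(missing)) {
    abort(sprintf("`%s` is missing feature(s): %s.", arg,
                  paste(missing, collapse = ", ")),
          class = "rtstress_missing_feature")
  }
  x[stress_feature_names()]
}

#' Label before-to-during feature changes
#'
#' A label is `TRUE` when the during-treatment feature moved *strictly* in
#' its stressful direction. Exact ties count as not stressful. An undefined
#' LF/HF (NA, from a zero-HF window) yields a `FALSE` label and is flagged
#' in the `flags` attribute rather than guessed.
#'
#' @param before,during feature sets (one-row tibble, named list or vector)
#'   containing at least the seven canonical features.
#' @param directions a direction table as returned by [stress_directions()];
#'   overridable for sensitivity analyses.
#' @return named logical vector of length 7 (attribute `flags` lists any
#'   features with undefined values).
#' @export
label_changes <- function(before, during, directions = stress_directions()) {
  b <- as_feature_vector(before, "before")
  d <- as_feature_vector(during, "during")
  dir <- directions$direction[match(stress_feature_names(), directions$feature)]
  delta <- d - b
  lab <- ifelse(dir == "increase", delta > 0, delta < 0)
  undef <- is.na(lab)
  lab[undef] <- FALSE
  names(lab) <- stress_feature_names()
  structure(lab, flags = names(lab)[undef])
}

#' Quantized stress score
#'
#' The fraction of the seven features that moved stressfully, as a
#' percentage rounded half-up to two decimals, so the only attainable values
#' are 0, 14.29, 28.57, 42.86, 57.14, 71.43, 85.71 and 100.
#'
#' @param labels logical vector of seven directional labels.
#' @return score in percent.
#' @export
stress_score <- function(labels) {
  labels <- as.logical(labels)
  if (length(labels) != 7L || anyNA(labels)) {
    abort("`labels` must be seven non-missing logicals.",
          class = "rtstress_bad_argument")
  }
  round_half_up(100 * sum(labels) / 7, 2)
}

#' Binary stress call
#'
#' "yes" when the score exceeds 50% (i.e. at least 4 of 7 features moved
#' stressfully); exactly 50 is unattainable from seven labels.
#'
#' @param score a quantized stress score (percent).
#' @return logical: `TRUE` for stressed.
#' @export
classify_stress <- function(score) {
  stopifnot(all(abs(score - round_half_up(100 * round(score * 7 / 100) / 7, 2)) < 1e-9))
  score > 50
}

#' Assess a whole case table
#'
#' Vectorized labelling/scoring over a cohort tibble with `before_*` and
#' `during_*` feature columns. Appends label columns `l_hr` ... `l_tp`, the
#' quantized `score` and the binary `stressed` call.
#'
#' @param cases tibble with `before_<feature>` and `during_<feature>`
#'   columns for the seven canonical features.
#' @param directions direction table, see [stress_directions()].
#' @return `cases` with 9 added columns.
#' @export
assess_cases <- function(cases, directions = stress_directions()) {
  feats <- stress_feature_names()
  need <- c(paste0("before_", feats), paste0("during_", feats))
  missing <- setdiff(need, names(cases))
  if (length(missing)) {
    abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")),
          class = "rtstress_missing_feature")
  }
  dir <- directions$direction[match(feats, directions$feature)]
  labs <- matrix(FALSE, nrow(cases), 7,
                 dimnames = list(NULL, paste0("l_", feats)))
  for (j in seq_along(feats)) {
    delta <- cases[[paste0("during_", feats[j])]] - cases[[paste0("before_", feats[j])]]
    lj <- if (dir[j] == "increase") delta > 0 else delta < 0
    lj[is.na(lj)] <- FALSE
    labs[, j] <- lj
  }
  k <- rowSums(labs)
  out <- bind_cols(cases, as_tibble(labs))
  out$score <- round_half_up(100 * k / 7, 2)
  out$stressed <- out$score > 50
  out
}

# Extract the n x 7 logical label matrix from a case table.
label_matrix <- function(cases) {
  cols <- paste0("l_", stress_feature_names())
  missing <- setdiff(cols, names(cases))
  if (length(missing)) {
    abort("Case table lacks label columns; run assess_cases() first.",
          class = "rtstress_bad_argument")
  }
  m <- as.matrix(cases[cols])
  storage.mode(m) <- "logical"
  m
}
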