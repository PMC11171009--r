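# Gaussian GEE (identity link) with an exchangeable working correlation and
# robust sandwich covariance, for repeated patient-day measurements.

#' Generalized estimating equations for a Gaussian outcome
#'
#' Marginal linear regression for clustered data: iteratively reweighted
#' estimation under a working correlation (exchangeable by default, with the
#' intra-cluster correlation estimated from Pearson residuals by moments),
#' followed by the robust sandwich covariance, which is consistent even when
#' the working structure is wrong.
#'
#' With tens rather than hundreds of clusters the plain sandwich is known to
#' be anti-conservative, so the usual finite-sample remedies are applied:
#' the meat is scaled by G/(G-1) and Wald inference uses t quantiles with
#' G - p degrees of freedom (G clusters, p coefficients).
#'
#' @param formula model formula.
#' @param data data frame.
#' @param id cluster identifier: a column name (string) or vector.
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param maxit,tol iteration control.
#' @return an object of class `rt_gee` with `coefficients`, `vcov` (robust,
#'   G/(G-1)-adjusted), `df` (residual degrees of freedom for t inference),
#'   `alpha`, `phi`, `n_clusters`.
#' @export
gee_gaussian <- function(formula, data, id, corstr = c("exchangeable", "independence"),
                         maxit = 50, tol = 1e-10) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  cluster <- if (is.character(id) && length(id) == 1L) data[[id]] else id
  cluster <- factor(cluster)
  if (length(cluster) != length(y)) {
    abort("Cluster id length must match the data.", class = "rtstress_bad_argument")
  }
  idx <- split(seq_along(y), cluster)
  p <- ncol(X)
  N <- length(y)
  if (any(apply(X[, colnames(X) != "(Intercept)", drop = FALSE], 2, sd0) == 0)) {
    abort("A model term is constant; the association is not identifiable.",
          class = "rtstress_degenerate_predictor")
  }

  beta <- stats::lm.fit(X, y)$coefficients
  alpha <- 0
  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ii in idx) {
        ni <- length(ii)
        if (ni < 2) next
        ri <- r[ii]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- if (den > p) num / phi / (den - p) else 0
      alpha <- min(max(alpha, 0), 0.99)
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Wi <- solve(Ri) / phi
      Xi <- X[ii, , drop = FALSE]
      A <- A + crossprod(Xi, Wi %*% Xi)
      b <- b + crossprod(Xi, Wi %*% y[ii])
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }

  r <- y - X %*% beta
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Wi <- solve(Ri) / phi
    Xi <- X[ii, , drop = FALSE]
    ui <- crossprod(Xi, Wi %*% r[ii])
    B <- B + crossprod(Xi, Wi %*% Xi)
    M <- M + tcrossprod(ui)
  }
  G <- length(idx)
  Binv <- solve(B)
  vcov <- Binv %*% (M * G / max(G - 1, 1)) %*% Binv
  beta <- drop(beta)
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vcov, alpha = alpha, phi = phi,
                 df = max(G - p, 1), n_clusters = G, n_obs = N,
                 formula = formula, corstr = corstr),
            class = "rt_gee")
}

#' @export
print.rt_gee <- function(x, ...) {
  cat(sprintf("<rt_gee> %s working correlation, %d clusters / %d obs (alpha = %.3f)\n",
              x$corstr, x$n_clusters, x$n_obs, x$alpha))
  print(tidy(x))
  invisible(x)
}

#' Tidy a GEE fit
#'
#' @param x an `rt_gee` object.
#' @param conf_level confidence level for the Wald intervals.
#' @param ... unused.
#' @return tibble with term, estimate, robust std.error, statistic, p.value,
#'   conf.low, conf.high.
#' @export
tidy.rt_gee <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  q <- stats::qt(1 - (1 - conf_level) / 2, df = x$df)
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pt(-abs(z), df = x$df)),
    conf.low = unname(x$coefficients - q * se),
    conf.high = unname(x$coefficients + q * se)
  )
}

#' @export
glance.rt_gee <- function(x, ...) {
  tibble(n_clusters = x$n_clusters, n_obs = x$n_obs, alpha = x$alpha,
         phi = x$phi, corstr = x$corstr)
}

#' Associate respiratory irregularity with stress
#'
#' Fits a marginal (GEE) linear model of irregularity on the stress
#' predictor with patients as clusters, exchangeable working correlation and
#' robust standard errors. The predictor is either the stress score per 10
#' points (`"score10"`) or the binary yes/no call (`"binary"`). With a
#' single cluster the fit falls back to ordinary least squares with
#' heteroskedasticity-robust errors and a warning.
#'
#' @param cases case tibble with `patient_id`, `score`, `stressed` and the
#'   irregularity column.
#' @param predictor `"score10"` or `"binary"`.
#' @param response irregularity column, `"phase_irr"` or `"amp_irr"`.
#' @return one-row tibble of class `rt_assoc`: `response`, `predictor_kind`,
#'   `beta`, `lcl`, `ucl`, `p_value`, `n_cases`, `n_patients`.
#' @export
associate_irregularity <- function(cases, predictor = c("score10", "binary"),
                                   response = c("phase_irr", "amp_irr")) {
  predictor <- match.arg(predictor)
  response <- response[1]
  if (!response %in% names(cases)) {
    abort(sprintf("Irregularity column '%s' not present.", response),
          class = "rtstress_bad_argument")
  }
  df <- cases[!is.na(cases[[response]]), ]
  df$.y <- df[[response]]
  df$.x <- if (predictor == "score10") df$score / 10 else as.numeric(df$stressed)
  n_cl <- length(unique(df$patient_id))
  kind <- if (predictor == "score10") "stress score per 10%" else "stress yes/no"
  if (sd0(df$.x) == 0) {
    warn(sprintf("Predictor '%s' has no variation; association undefined.", kind),
         class = "rtstress_degenerate_predictor")
    est <- NA_real_; lcl <- NA_real_; ucl <- NA_real_; pv <- NA_real_
  } else if (n_cl < 2) {
    warn("Single patient cluster: falling back to OLS with robust errors.",
         class = "rtstress_single_cluster")
    fit <- lm(.y ~ .x, data = df)
    se <- sqrt(sandwich::vcovHC(fit, type = "HC1")[".x", ".x"])
    est <- unname(coef(fit)[".x"])
    q <- stats::qt(0.975, df = fit$df.residual)
    lcl <- est - q * se; ucl <- est + q * se
    pv <- 2 * stats::pt(-abs(est / se), df = fit$df.residual)
  } else {
    fit <- gee_gaussian(.y ~ .x, df, id = df$patient_id)
    row <- tidy(fit)[2, ]
    est <- row$estimate; lcl <- row$conf.low; ucl <- row$conf.high
    pv <- row$p.value
  }
  out <- tibble(
    response = response,
    predictor_kind = kind,
    beta = est, lcl = lcl, ucl = ucl, p_value = pv,
    n_cases = nrow(df),
    n_patients = n_cl
  )
  class(out) <- c("rt_assoc", class(out))
  out
}

#' Irregularity association table
#'
#' All four association fits (phase/amplitude x score-per-10%/binary) in one
#' table shaped like a Beta / LCL / UCL / p report.
#'
#' @param cases case tibble with irregularity columns.
#' @return tibble with one row per response x predictor combination.
#' @export
irregularity_table <- function(cases) {
  combos <- tidyr::expand_grid(response = c("phase_irr", "amp_irr"),
                               predictor = c("score10", "binary"))
  purrr::pmap(combos, function(response, predictor) {
    associate_irregularity(cases, predictor, response)
  }) |> bind_rows()
}
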