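# Shared fixtures, all generated in code.

# NN series with a fixed interval pattern (ms) laid end to end from t = 0.
nn_from_intervals <- function(nn_ms) {
  rt_nn(c(0, cumsum(nn_ms) / 1000), nn_ms)
}

# Alternating 950/1050 ms series of length n.
alternating_nn <- function(n = 300) {
  nn_from_intervals(rep(c(950, 1050), length.out = n))
}

# Tachogram modulated by pure sinusoidal tones: nn_i = 1000 + sum of
# amp * sin(2 pi f t_i), built iteratively so beat times stay consistent.
tone_nn <- function(freqs, amps, duration = 300) {
  t <- 0; times <- 0
  while (tail(times, 1) < duration) {
    rr <- 1000 + sum(amps * sin(2 * pi * freqs * tail(times, 1)))
    times <- c(times, tail(times, 1) + rr / 1000)
  }
  rt_nn(times)
}

# Case table with an exact number of TRUE labels per case.
cases_with_k_true <- function(ks) {
  feats <- stress_feature_names()
  labs <- t(vapply(ks, function(k) seq_len(7) <= k, logical(7)))
  colnames(labs) <- paste0("l_", feats)
  out <- tibble::as_tibble(labs)
  out$score <- vapply(seq_along(ks), function(i) stress_score(labs[i, ]), numeric(1))
  out$stressed <- out$score > 50
  out
}

# Dataset whose targets are a deterministic threshold function of the
# before-treatment features (learnable), used for prediction sanity checks.
deterministic_dataset <- function(n, seed) {
  co <- generate_cohort(cohort_config(n_patients = ceiling(n / 3),
                                      days_per_patient = c(3, 3), seed = seed))
  co <- co[seq_len(n), ]
  ds <- build_dataset(co, 1)
  med <- apply(ds$inputs, 2, median)
  ds$targets <- t(apply(ds$inputs, 1, function(r) r > med))
  colnames(ds$targets) <- paste0("l_", stress_feature_names())
  ds
}

# Brute-force multi-label metrics used as the independent oracle.
brute_multilabel <- function(pred, true) {
  n <- nrow(pred)
  acc <- prec <- rec <- f1 <- numeric(n); exact <- logical(n)
  for (i in seq_len(n)) {
    p <- which(pred[i, ]); t_ <- which(true[i, ])
    inter <- length(intersect(p, t_)); uni <- length(union(p, t_))
    exact[i] <- setequal(p, t_)
    acc[i] <- if (uni == 0) 1 else inter / uni
    prec[i] <- if (!length(p)) ifelse(!length(t_), 1, 0) else inter / length(p)
    rec[i] <- if (!length(t_)) ifelse(!length(p), 1, 0) else inter / length(t_)
    f1[i] <- if (!length(p) && !length(t_)) 1 else
      if (inter == 0) 0 else 2 * inter / (length(p) + length(t_))
  }
  list(emr = mean(exact), accuracy = mean(acc), recall = mean(rec),
       precision = mean(prec), f1 = mean(f1))
}
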