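# Dataset variants, fold construction, model fitting, evaluation metrics.

test_that("dataset variants have the documented widths and encodings", {
  co <- generate_cohort(cohort_config(seed = 11))
  widths <- c(7, 8, 8, 8, 9, 9, 9, 10)
  for (ty in 1:8) {
    ds <- build_dataset(co, ty)
    expect_equal(ncol(ds$inputs), widths[ty], info = paste("type", ty))
  }
  ds8 <- build_dataset(co, 8)
  expect_true(all(ds8$inputs[, "sex"] %in% c(0, 1)))
  expect_identical(colnames(ds8$inputs)[1:7], stress_feature_names())
  expect_error(build_dataset(dplyr::select(co, -"age"), 5),
               class = "rtstress_missing_covariate")
  expect_error(build_dataset(co, 9), class = "rtstress_bad_argument")
})

test_that("10-fold split of 123 cases gives fold sizes 12 and 13", {
  f <- make_folds(123, 10, seed = 1)
  expect_identical(sort(as.integer(table(f))), sort(c(rep(12L, 7), rep(13L, 3))))
  expect_identical(make_folds(123, 10, seed = 1), make_folds(123, 10, seed = 1))
  expect_error(make_folds(5, 10), class = "rtstress_bad_argument")
})

test_that("grouped folds never split a patient and leave-one-out works", {
  co <- generate_cohort(cohort_config(seed = 12))
  ds <- build_dataset(co, 1)
  f <- make_folds(nrow(ds$inputs), 10, seed = 2, groups = ds$groups)
  per_patient <- tapply(f, ds$groups, function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
  n <- 20
  f_loo <- make_folds(n, n, seed = 3)
  expect_identical(sort(unique(f_loo)), 1:20)
  expect_true(all(table(f_loo) == 1))
})

test_that("multi-label metrics equal an exhaustive hand computation", {
  pred <- rbind(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
                rep(FALSE, 7),
                c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  true <- rbind(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
                rep(FALSE, 7),
                c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  got <- evaluate_multilabel(pred, true)
  oracle <- brute_multilabel(pred, true)
  for (m in names(oracle)) {
    expect_equal(got$example[got$metric == m], oracle[[m]], info = m)
  }
  expect_equal(got$example[got$metric == "emr"], 1 / 3)
  # micro metrics from pooled confusion counts
  expect_equal(got$micro[got$metric == "accuracy"], 17 / 21)
  expect_equal(got$micro[got$metric == "precision"], 3 / 5)
  expect_error(evaluate_multilabel(pred, true[1:2, ]),
               class = "rtstress_bad_argument")
})

test_that("EMR never exceeds example-based accuracy on random label matrices", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    pred <- matrix(runif(n * 7) > runif(1, 0.2, 0.8), n, 7)
    true <- matrix(runif(n * 7) > runif(1, 0.2, 0.8), n, 7)
    ev <- evaluate_multilabel(pred, true)
    expect_lte(ev$example[ev$metric == "emr"],
               ev$example[ev$metric == "accuracy"] + 1e-12)
    expect_true(all(ev$example >= 0 & ev$example <= 1))
  }
})

test_that("binary metrics come from the derived yes/no calls", {
  truth <- c(rep(TRUE, 7), rep(FALSE, 6))
  pred <- truth; pred[c(3, 11)] <- !pred[c(3, 11)]   # 11 of 13 correct
  ev <- evaluate_binary(pred, truth)
  expect_equal(round(ev$accuracy, 3), 0.846)
  expect_equal(ev$n_cases, 13)

  all_yes <- evaluate_binary(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(all_yes$recall, 1)

  expect_warning(ev0 <- evaluate_binary(rep(FALSE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE)),
                 class = "rtstress_degenerate_precision")
  expect_equal(ev0$precision, 0)

  # label matrices reduce through the quantized score
  labs_yes <- matrix(rep(c(rep(TRUE, 5), FALSE, FALSE), 2), 2, 7, byrow = TRUE)
  labs_no <- matrix(FALSE, 2, 7)
  expect_equal(evaluate_binary(labs_yes, labs_yes)$accuracy, 1)
  expect_equal(evaluate_binary(labs_yes, labs_no)$accuracy, 0)
})

test_that("a leaked target column drives held-out EMR to 1", {
  co <- generate_cohort(cohort_config(seed = 11))
  ds <- build_dataset(co, 1)
  ds$inputs <- cbind(ds$inputs, ds$targets * 1)
  ev <- crossvalidate(ds, "tree", k = 5, seed = 3)
  expect_equal(glance(ev)$emr, 1)
})

test_that("models sit at the base rate when targets are independent of inputs", {
  co <- generate_cohort(cohort_config(n_patients = 60, days_per_patient = c(3, 3),
                                      seed = 31))
  ds <- build_dataset(co, 1)
  set.seed(5)
  ds$targets <- ds$targets[sample(nrow(ds$targets)), ]
  ev <- crossvalidate(ds, "forest", k = 5, seed = 6, grouped = FALSE)
  base <- colMeans(ds$targets)
  chance <- mean(pmax(base, 1 - base))
  se <- sqrt(chance * (1 - chance) / (nrow(ds$targets) * 7))
  expect_lt(glance(ev)$micro_accuracy, chance + 3 * se)
})

test_that("fits are deterministic given the seed, for every model family", {
  co <- generate_cohort(cohort_config(n_patients = 12, days_per_patient = c(2, 2),
                                      seed = 7))
  ds <- build_dataset(co, 8)
  for (m in model_specs()) {
    p1 <- fit_predict(ds, m, seed = 4, train = 1:18, test = 19:24)
    p2 <- fit_predict(ds, m, seed = 4, train = 1:18, test = 19:24)
    expect_identical(p1, p2, info = m)
    expect_identical(dim(p1), c(6L, 7L))
  }
})

test_that("single-class training labels give a constant prediction with warning", {
  co <- generate_cohort(cohort_config(n_patients = 10, p_stress = 1, seed = 5))
  ds <- build_dataset(co, 1)
  w <- capture_warnings(p <- fit_predict(ds, "tree", seed = 1))
  expect_length(w, 7)   # one warning per degenerate label column
  expect_true(all(grepl("single-class", w)))
  expect_true(all(p))
})

test_that("sequence models train and evaluate end to end", {
  ds <- deterministic_dataset(60, 77)
  for (m in c("rnn", "attention")) {
    ev <- crossvalidate(ds, m, k = 3, seed = 2, grouped = FALSE)
    g <- glance(ev)
    expect_true(all(g$accuracy >= 0 & g$accuracy <= 1))
    # deterministic targets are learnable well above the ~0.5 base rate
    expect_gt(g$micro_accuracy, 0.6)
  }
})
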