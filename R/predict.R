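# Dataset variants, baseline multi-label models, cross-validation and the
# evaluation metrics (exact match ratio + example-based / micro-averaged
# classification metrics).

covariates_for_type <- function(dataset_type) {
  switch(as.character(dataset_type),
         "1" = character(0),
         "2" = "age",
         "3" = "sex",
         "4" = "day",
         "5" = c("age", "sex"),
         "6" = c("age", "day"),
         "7" = c("sex", "day"),
         "8" = c("age", "sex", "day"),
         abort("`dataset_type` must be 1..8.", class = "rtstress_bad_argument"))
}

#' Build a prediction dataset variant
#'
#' The eight input variants all contain the seven before-treatment features
#' (fixed order: hr, sdnn, rmssd, pnn50, hf, lf_hf, tp) and add covariates:
#' Type 1 none; 2 age; 3 sex; 4 day; 5 age+sex; 6 age+day; 7 sex+day;
#' 8 age+sex+day. Sex is encoded 0/1 (male = 1), day as an integer. Targets
#' are the seven during-treatment directional labels.
#'
#' @param cases assessed cohort tibble (see [generate_cohort()] /
#'   [assess_cases()]).
#' @param dataset_type integer 1-8.
#' @return list of class `rt_dataset`: `inputs` (numeric matrix), `targets`
#'   (logical matrix n x 7), `groups` (patient ids), `dataset_type`.
#' @export
build_dataset <- function(cases, dataset_type = 1) {
  covs <- covariates_for_type(dataset_type)
  missing <- setdiff(covs, names(cases))
  if (length(missing)) {
    abort(sprintf("Dataset type %s needs covariate(s): %s.", dataset_type,
                  paste(missing, collapse = ", ")),
          class = "rtstress_missing_covariate")
  }
  feats <- paste0("before_", stress_feature_names())
  missing_f <- setdiff(feats, names(cases))
  if (length(missing_f)) {
    abort(paste0("Missing feature column(s): ", paste(missing_f, collapse = ", ")),
          class = "rtstress_missing_feature")
  }
  X <- as.matrix(cases[feats])
  colnames(X) <- stress_feature_names()
  for (cv in covs) {
    col <- if (cv == "sex") as.numeric(cases$sex == "M") else as.numeric(cases[[cv]])
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  structure(list(inputs = X,
                 targets = label_matrix(cases),
                 groups = as.character(cases$patient_id),
                 dataset_type = dataset_type),
            class = "rt_dataset")
}

#' @export
print.rt_dataset <- function(x, ...) {
  cat(sprintf("<rt_dataset> Type %s: %d cases x %d inputs, 7 targets, %d patients\n",
              x$dataset_type, nrow(x$inputs), ncol(x$inputs),
              length(unique(x$groups))))
  invisible(x)
}

model_specs <- function() c("tree", "forest", "svm", "rnn", "attention")

# z-score train columns; apply the same transform to test. Constant columns
# are left centred only.
zscore_fit <- function(Xtr) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd0)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
zscore_apply <- function(X, z) sweep(sweep(X, 2, z$mu), 2, z$sd, "/")

# Fit one model family on (Xtr, Ytr) and predict logical labels for Xte.
fit_predict_matrix <- function(Xtr, Ytr, Xte, model_spec, seed) {
  K <- ncol(Ytr)
  pred <- matrix(FALSE, nrow(Xte), K, dimnames = list(NULL, colnames(Ytr)))
  if (model_spec %in% c("svm", "rnn", "attention")) {
    z <- zscore_fit(Xtr)
    Xtr <- zscore_apply(Xtr, z)
    Xte <- zscore_apply(Xte, z)
  }
  if (model_spec %in% c("rnn", "attention")) {
    par <- train_seqnet(model_spec, Xtr, Ytr * 1, seed = seed)
    return(predict_seqnet(model_spec, par, Xte))
  }
  for (k in seq_len(K)) {
    yk <- factor(Ytr[, k], levels = c(FALSE, TRUE))
    if (length(unique(Ytr[, k])) < 2L) {
      warn(sprintf("Label %d is single-class in training; predicting the constant.",
                   k), class = "rtstress_degenerate_label")
      pred[, k] <- Ytr[1, k]
      next
    }
    df_tr <- data.frame(Xtr); df_tr$.y <- yk
    df_te <- data.frame(Xte)
    pred[, k] <- switch(
      model_spec,
      tree = {
        fit <- rpart::rpart(.y ~ ., df_tr, method = "class",
                            control = rpart::rpart.control(xval = 0))
        predict(fit, df_te, type = "class") == "TRUE"
      },
      forest = {
        fit <- ranger::ranger(.y ~ ., df_tr, num.trees = 300, seed = seed + k,
                              respect.unordered.factors = TRUE)
        predict(fit, df_te)$predictions == "TRUE"
      },
      svm = {
        fit <- e1071::svm(.y ~ ., df_tr, kernel = "radial", scale = FALSE)
        predict(fit, df_te) == "TRUE"
      },
      abort(sprintf("Unknown model '%s'.", model_spec),
            class = "rtstress_bad_argument")
    )
  }
  pred
}

#' Fit a multi-label model and predict labels
#'
#' Model families: `"tree"` (one CART per label), `"forest"` (one random
#' forest per label), `"svm"` (one RBF support-vector machine per label,
#' inputs z-scored on the training split), `"rnn"` (Elman recurrent network
#' reading the input vector as an ordered univariate sequence) and
#' `"attention"` (single-head self-attention network, same sequence view).
#' Training is deterministic given `seed`.
#'
#' @param dataset an `rt_dataset` from [build_dataset()].
#' @param model_spec one of [model_specs()].
#' @param seed integer seed.
#' @param train,test row indices; both default to every case.
#' @return logical matrix (length(test) x 7) of predicted labels.
#' @export
fit_predict <- function(dataset, model_spec = "forest", seed = 1,
                        train = NULL, test = NULL) {
  model_spec <- match.arg(model_spec, model_specs())
  train <- train %||% seq_len(nrow(dataset$inputs))
  test <- test %||% train
  with_local_seed(seed, {
    fit_predict_matrix(dataset$inputs[train, , drop = FALSE],
                       dataset$targets[train, , drop = FALSE],
                       dataset$inputs[test, , drop = FALSE],
                       model_spec, seed)
  })
}

#' Cross-validation fold assignment
#'
#' Plain mode deals cases round-robin after a seeded shuffle (123 cases over
#' 10 folds gives sizes 12 and 13); grouped mode keeps every patient's cases
#' in a single fold by greedily assigning shuffled patients to the currently
#' smallest fold.
#'
#' @param n number of cases.
#' @param k number of folds.
#' @param seed integer seed.
#' @param groups optional patient ids (length n) for grouped folds.
#' @return integer vector of fold labels in 1..k.
#' @export
make_folds <- function(n, k = 10, seed = 1, groups = NULL) {
  if (k > n) abort("k must not exceed the number of cases.",
                   class = "rtstress_bad_argument")
  with_local_seed(seed, {
    if (is.null(groups)) {
      sample(rep(seq_len(k), length.out = n))
    } else {
      stopifnot(length(groups) == n)
      sizes <- rep(0L, k)
      fold_of <- integer(0)
      for (g in sample(unique(groups))) {
        f <- which.min(sizes)
        sizes[f] <- sizes[f] + sum(groups == g)
        fold_of[g] <- f
      }
      unname(fold_of[groups])
    }
  })
}

#' Multi-label evaluation metrics
#'
#' Exact match ratio (all seven labels right) plus accuracy, recall,
#' precision and F1 under two averaging modes: *example-based* (per-case
#' Jaccard accuracy and per-case P/R/F1, averaged over cases; a case with no
#' true and no predicted labels counts 1) and *micro* (pooled over all label
#' cells; micro accuracy is cell-wise/Hamming accuracy).
#'
#' @param pred,true logical matrices of equal dimension.
#' @return tibble with columns `metric`, `example`, `micro`.
#' @export
evaluate_multilabel <- function(pred, true) {
  pred <- as.matrix(pred); true <- as.matrix(true)
  if (!all(dim(pred) == dim(true))) {
    abort("Prediction and truth shapes differ.", class = "rtstress_bad_argument")
  }
  storage.mode(pred) <- "logical"; storage.mode(true) <- "logical"
  inter <- rowSums(pred & true)
  uni <- rowSums(pred | true)
  np <- rowSums(pred); nt <- rowSums(true)
  acc_i <- ifelse(uni == 0, 1, inter / uni)
  prec_i <- ifelse(np == 0, ifelse(nt == 0, 1, 0), inter / np)
  rec_i <- ifelse(nt == 0, ifelse(np == 0, 1, 0), inter / nt)
  f1_i <- ifelse(np + nt == 0, 1, 2 * inter / (np + nt))

  tp <- sum(pred & true); fp <- sum(pred & !true); fn <- sum(!pred & true)
  tn <- sum(!pred & !true)
  micro_p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  micro_r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  micro_f <- if (micro_p + micro_r == 0) 0 else
    2 * micro_p * micro_r / (micro_p + micro_r)

  tibble(
    metric = c("emr", "accuracy", "recall", "precision", "f1"),
    example = c(mean(rowSums(pred == true) == ncol(true)),
                mean(acc_i), mean(rec_i), mean(prec_i), mean(f1_i)),
    micro = c(mean(rowSums(pred == true) == ncol(true)),
              (tp + tn) / (tp + tn + fp + fn), micro_r, micro_p, micro_f)
  )
}

#' Binary stress-classification metrics
#'
#' Reduces each seven-label row to the quantized score and the yes/no call
#' (score > 50), then reports accuracy, recall, precision and F1 on the
#' binary calls. With positives present but none predicted, precision is
#' reported as 0 with a warning.
#'
#' @param pred,true logical label matrices (n x 7), or logical vectors of
#'   already-derived yes/no calls.
#' @return one-row tibble: `accuracy`, `recall`, `precision`, `f1`,
#'   `n_cases`.
#' @export
evaluate_binary <- function(pred, true) {
  to_call <- function(m) {
    if (is.matrix(m) || is.data.frame(m)) {
      apply(as.matrix(m), 1, function(r) classify_stress(stress_score(r)))
    } else {
      as.logical(m)
    }
  }
  yp <- to_call(pred); yt <- to_call(true)
  if (length(yp) != length(yt)) {
    abort("Prediction and truth shapes differ.", class = "rtstress_bad_argument")
  }
  tp <- sum(yp & yt); fp <- sum(yp & !yt); fn <- sum(!yp & yt)
  precision <- if (tp + fp == 0) {
    if (any(yt)) warn("No positive predictions; precision reported as 0.",
                      class = "rtstress_degenerate_precision")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(accuracy = mean(yp == yt), recall = recall, precision = precision,
         f1 = f1, n_cases = length(yp))
}

#' k-fold cross-validation of a multi-label stress predictor
#'
#' Fits the chosen model on k-1 folds and evaluates on the held-out fold,
#' reporting both the multi-label metrics (EMR, accuracy, recall, precision,
#' F1; example-based and micro averaging) and the derived binary
#' stress-classification metrics, per fold and averaged.
#'
#' @param dataset an `rt_dataset`.
#' @param model_spec one of [model_specs()].
#' @param k number of folds (default 10).
#' @param seed integer seed controlling folds and model fits.
#' @param grouped keep all of a patient's cases in one fold (default `TRUE`;
#'   set `FALSE` for plain case-level folds).
#' @return object of class `rt_eval`: list with `folds` (per-fold tibble),
#'   `summary` (mean over folds), `model_spec`, `dataset_type`, `k`.
#' @export
crossvalidate <- function(dataset, model_spec = "forest", k = 10, seed = 1,
                          grouped = TRUE) {
  model_spec <- match.arg(model_spec, model_specs())
  n <- nrow(dataset$inputs)
  folds <- make_folds(n, k, seed, groups = if (grouped) dataset$groups)
  per_fold <- purrr::map(sort(unique(folds)), function(f) {
    test <- which(folds == f); train <- which(folds != f)
    pred <- fit_predict(dataset, model_spec, seed = child_seed(seed, f),
                        train = train, test = test)
    ml <- evaluate_multilabel(pred, dataset$targets[test, , drop = FALSE])
    bn <- evaluate_binary(pred, dataset$targets[test, , drop = FALSE])
    tibble(
      fold = f, n_test = length(test),
      emr = ml$example[ml$metric == "emr"],
      accuracy = ml$example[ml$metric == "accuracy"],
      recall = ml$example[ml$metric == "recall"],
      precision = ml$example[ml$metric == "precision"],
      f1 = ml$example[ml$metric == "f1"],
      micro_accuracy = ml$micro[ml$metric == "accuracy"],
      micro_f1 = ml$micro[ml$metric == "f1"],
      bin_accuracy = bn$accuracy, bin_recall = bn$recall,
      bin_precision = bn$precision, bin_f1 = bn$f1
    )
  }) |> bind_rows()
  summary <- per_fold |>
    select(-"fold", -"n_test") |>
    dplyr::summarise(across(dplyr::everything(), mean))
  structure(list(folds = per_fold, summary = summary,
                 model_spec = model_spec, dataset_type = dataset$dataset_type,
                 k = k, grouped = grouped, averaging_mode = "example-based"),
            class = "rt_eval")
}

#' @export
print.rt_eval <- function(x, ...) {
  cat(sprintf("<rt_eval> %s, Type %s dataset, %d-fold CV (%s folds)\n",
              x$model_spec, x$dataset_type, x$k,
              if (x$grouped) "patient-grouped" else "case-level"))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.rt_eval <- function(x, ...) x$folds

#' @export
glance.rt_eval <- function(x, ...) {
  bind_cols(tibble(model = x$model_spec, dataset_type = x$dataset_type),
            x$summary)
}
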