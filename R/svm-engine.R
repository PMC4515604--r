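# Support-vector models with an RBF kernel, length-stratified routing,
# leave-one-out cross-validation, and threshold-wise performance. e1071
# (libsvm) does the quadratic programming; feature standardization,
# cross-validation, metrics and thresholding are handled here so that fold
# statistics never leak.

#' @importFrom e1071 svm
NULL

DEFAULT_GRID <- list(cost = c(0.1, 1, 10, 100),
                     gamma = c(0.001, 0.01, 0.1, 1),
                     epsilon = c(0.1, 0.5))

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1  # constant columns pass through unscaled
  list(center = mu, scale = sdv)
}

apply_scaler <- function(X, scaler) {
  scale(X, center = scaler$center, scale = scaler$scale)
}

fit_svm_raw <- function(X, y, task, hyper) {
  if (task == "regression") {
    e1071::svm(X, y, type = "eps-regression", kernel = "radial",
               cost = hyper$cost, gamma = hyper$gamma, epsilon = hyper$epsilon,
               scale = FALSE)
  } else {
    e1071::svm(X, factor(y, levels = c(0, 1)), type = "C-classification",
               kernel = "radial", cost = hyper$cost, gamma = hyper$gamma,
               scale = FALSE)
  }
}

# decision values oriented so that larger always means class "1"
decision_scores <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
}

check_dataset <- function(data, outcome, features, task) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(features %in% names(data)))
  if (task == "classification" && dplyr::n_distinct(data[[outcome]]) < 2) {
    abort("Classification needs both classes present.",
          class = "ahtpep_error_single_class")
  }
  if (nrow(data) < 10) {
    abort(sprintf("Need at least 10 samples, got %d.", nrow(data)),
          class = "ahtpep_error_too_few_samples")
  }
  invisible(TRUE)
}

default_hyper <- function(task, hyper = NULL) {
  base <- list(cost = 10, gamma = 0.01, epsilon = 0.1)
  if (!is.null(hyper)) base[names(hyper)] <- hyper
  base
}

#' Train a support-vector model for one length category
#'
#' Fits an RBF-kernel SVM -- epsilon-regression of pIC50 for tiny peptides,
#' binary C-classification (AHT vs non-AHT, labels 1/0) otherwise. Features
#' are standardized to zero mean and unit variance with statistics from the
#' training data; the scaler is stored with the model and re-applied at
#' prediction. Hyperparameters can be given, or chosen by a leave-one-out
#' grid search over `grid` when `tune = TRUE`. For classification the
#' deployed decision threshold is the accuracy-maximizing threshold of the
#' training LOOCV scan (falling back to 0 when `tune = FALSE`).
#'
#' @param data Data frame with feature columns and the outcome column.
#' @param outcome Name of the outcome column (numeric pIC50, or 0/1 labels).
#' @param features Feature column names; defaults to the encoder's
#'   `feature_spec` attribute, else all numeric columns except the outcome.
#' @param task `"regression"` or `"classification"`; inferred from the
#'   outcome when `"auto"` (0/1-valued outcomes classify).
#' @param hyper Named list overriding `cost`, `gamma`, `epsilon`.
#' @param tune Run the LOOCV grid search (default `FALSE`, using `hyper`
#'   on top of documented defaults cost 10, gamma 0.01, epsilon 0.1).
#' @param grid Search grid for `tune = TRUE` (default `DEFAULT_GRID`:
#'   cost 0.1/1/10/100, gamma 0.001/0.01/0.1/1, epsilon 0.1/0.5).
#' @param category Optional length-category tag for routing bundles.
#' @param seed Integer recorded in the model's training fingerprint.
#' @return An object of class `ahtpep_model`.
#' @export
aht_train <- function(data, outcome, features = NULL,
                      task = c("auto", "regression", "classification"),
                      hyper = NULL, tune = FALSE, grid = DEFAULT_GRID,
                      category = NULL, seed = 1L) {
  task <- match.arg(task)
  features <- sort(numeric_feature_cols(
    data, features %||% setdiff(numeric_feature_cols(data), outcome)))
  features <- setdiff(features, outcome)
  y <- data[[outcome]]
  if (task == "auto") {
    task <- if (all(y %in% c(0, 1))) "classification" else "regression"
  }
  check_dataset(data, outcome, features, task)
  X <- as.matrix(data[features])
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)

  if (tune) {
    hyper <- tune_hyper(data, outcome, features, task, grid)
  } else {
    hyper <- default_hyper(task, hyper)
  }
  fit <- fit_svm_raw(Xs, y, task, hyper)

  threshold <- 0
  eval_report <- NULL
  if (task == "classification" && tune) {
    eval_report <- aht_loocv(data, outcome, features, task, hyper)
    threshold <- attr(eval_report$threshold_table, "best_acc_threshold")
  }
  structure(list(
    fit = fit, scaler = scaler, task = task, features = features,
    outcome = outcome, hyper = hyper, threshold = threshold,
    category = category, spec = feature_spec(data),
    fingerprint = list(n = nrow(data), seed = as.integer(seed),
                       dataset_hash = rlang::hash(list(data[features], y))),
    loocv = eval_report
  ), class = "ahtpep_model")
}

tune_hyper <- function(data, outcome, features, task, grid) {
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        epsilon = if (task == "regression") grid$epsilon else 0.1,
                        KEEP.OUT.ATTRS = FALSE)
  score <- vapply(seq_len(nrow(combos)), function(i) {
    ev <- aht_loocv(data, outcome, features, task, as.list(combos[i, ]))
    g <- glance(ev)
    if (task == "regression") g$r else g$acc
  }, numeric(1))
  best <- which.max(score)  # first (lowest-index) combo wins ties
  as.list(combos[best, ])
}

#' @export
print.ahtpep_model <- function(x, ...) {
  cat(sprintf("<ahtpep %s SVM (rbf): %d features, n = %d%s>\n",
              x$task, length(x$features), x$fingerprint$n,
              if (is.null(x$category)) "" else paste0(", category ", x$category)))
  invisible(x)
}

#' Predict from a trained model
#'
#' `newdata` may carry the model's feature columns already, or just a
#' `sequence` column, in which case the peptides are re-encoded with the
#' feature spec stored in the model (amino-acid composition, atomic
#' composition or scale features; externally supplied descriptor tables
#' cannot be re-derived and must be provided as columns).
#'
#' @param object An `ahtpep_model`.
#' @param newdata Data frame (or character vector of sequences).
#' @param ... Unused.
#' @return A tibble: regression gives `pic50` and `ic50_uM`; classification
#'   gives `score`, `call` (1 = AHT at the stored threshold) and `threshold`.
#' @export
predict.ahtpep_model <- function(object, newdata, ...) {
  newdata <- encode_for_model(object, newdata)
  X <- apply_scaler(as.matrix(newdata[object$features]), object$scaler)
  if (object$task == "regression") {
    p <- as.numeric(stats::predict(object$fit, X))
    tibble::tibble(pic50 = p, ic50_uM = pic50_to_ic50(p))
  } else {
    s <- decision_scores(object$fit, X)
    tibble::tibble(score = s, call = as.integer(s >= object$threshold),
                   threshold = object$threshold)
  }
}

encode_for_model <- function(model, newdata) {
  if (is.character(newdata)) newdata <- tibble::tibble(sequence = newdata)
  if (all(model$features %in% names(newdata))) return(newdata)
  spec <- model$spec
  if (is.null(spec)) {
    abort("newdata lacks the model's feature columns and the model has no feature spec to re-encode with.",
          class = "ahtpep_error_input")
  }
  encoded <- switch(spec$family,
    aac = encode_aac(newdata),
    atomic = encode_atomic(newdata, mode = spec$params$mode %||% "residue_sum",
                           include_bonds = isTRUE(spec$params$include_bonds)),
    scales = encode_scales(newdata, pooling = spec$params$pooling %||% "mean"),
    abort(sprintf("Cannot re-encode '%s' features from sequences; supply the columns.",
                  spec$family), class = "ahtpep_error_input")
  )
  encoded
}

#' Leave-one-out cross-validation
#'
#' Retrains on every size n-1 subset and predicts the held-out sample, so
#' each of the n predictions comes from a model that never saw that sample.
#' The feature scaler is refit inside every fold. Metrics are computed on
#' the pooled held-out predictions: Pearson R and RMSE for regression;
#' sensitivity, specificity, accuracy and MCC over a threshold scan of the
#' decision scores for classification.
#'
#' @inheritParams aht_train
#' @return An object of class `ahtpep_eval`: per-sample predictions plus
#'   pooled metrics (and, for classification, the threshold table).
#' @export
aht_loocv <- function(data, outcome, features = NULL,
                      task = c("auto", "regression", "classification"),
                      hyper = NULL) {
  task <- match.arg(task)
  features <- sort(numeric_feature_cols(
    data, features %||% setdiff(numeric_feature_cols(data), outcome)))
  features <- setdiff(features, outcome)
  y <- data[[outcome]]
  if (task == "auto") {
    task <- if (all(y %in% c(0, 1))) "classification" else "regression"
  }
  check_dataset(data, outcome, features, task)
  hyper <- default_hyper(task, hyper)
  X <- as.matrix(data[features])
  n <- nrow(X)
  held_out <- vapply(seq_len(n), function(i) {
    scaler <- fit_scaler(X[-i, , drop = FALSE])
    fit <- fit_svm_raw(apply_scaler(X[-i, , drop = FALSE], scaler),
                       y[-i], task, hyper)
    Xi <- apply_scaler(X[i, , drop = FALSE], scaler)
    if (task == "regression") as.numeric(stats::predict(fit, Xi))
    else decision_scores(fit, Xi)
  }, numeric(1))
  predictions <- tibble::tibble(
    row = seq_len(n), truth = y,
    prediction = if (task == "regression") held_out else NA_real_,
    score = if (task == "classification") held_out else NA_real_
  )
  if (task == "regression") {
    metrics <- regression_metrics(y, held_out)
    tt <- NULL
  } else {
    tt <- threshold_scan(held_out, y)
    at0 <- classification_metrics(
      tp = sum(held_out >= 0 & y == 1), fp = sum(held_out >= 0 & y == 0),
      tn = sum(held_out < 0 & y == 0), fn = sum(held_out < 0 & y == 1)
    )
    metrics <- at0
  }
  structure(list(predictions = predictions, task = task, metrics = metrics,
                 threshold_table = tt, hyper = hyper, n = n),
            class = "ahtpep_eval")
}

#' @export
print.ahtpep_eval <- function(x, ...) {
  cat(sprintf("<ahtpep LOOCV report: %s, n = %d>\n", x$task, x$n))
  print(glance(x))
  invisible(x)
}

#' Regression performance: Pearson R and RMSE
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 3); `y_true`
#'   must not be constant.
#' @return A one-row tibble with `r` and `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  if (stats::sd(y_true) == 0) {
    abort("Correlation undefined for constant truth.",
          class = "ahtpep_error_constant_truth")
  }
  tibble::tibble(
    r = if (stats::sd(y_pred) == 0) 0 else stats::cor(y_true, y_pred),
    rmse = sqrt(mean((y_true - y_pred)^2))
  )
}

#' Classification performance from a contingency table
#'
#' Sensitivity, specificity and accuracy in percent; Matthews correlation
#' coefficient in \[-1, 1\], defined as 0 whenever any marginal of the
#' contingency table is empty (the conventional completion). MCC of 1 is a
#' perfect prediction, 0 a random one. Vectorized over tables.
#'
#' @param tp,fp,tn,fn Non-negative counts; each truth class must be
#'   non-empty (`tp + fn > 0`, `tn + fp > 0`).
#' @return A tibble with `sn`, `sp`, `acc` (percent) and `mcc`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  if (any(c(tp, fp, tn, fn) < 0)) {
    abort("Counts must be non-negative.", class = "ahtpep_error_input")
  }
  if (any(tp + fn == 0)) {
    abort("No positive examples (tp + fn = 0).", class = "ahtpep_error_no_positives")
  }
  if (any(tn + fp == 0)) {
    abort("No negative examples (tn + fp = 0).", class = "ahtpep_error_no_negatives")
  }
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(denom == 0, 0, (tp * tn - fp * fn) / denom)
  tibble::tibble(
    sn = 100 * tp / (tp + fn),
    sp = 100 * tn / (tn + fp),
    acc = 100 * (tp + tn) / (tp + fp + tn + fn),
    mcc = mcc
  )
}

#' Threshold-wise classification performance
#'
#' Sweeps a decision threshold over the score range (default grid: 0.1
#' steps from just below the minimum to just above the maximum score,
#' always including 0, the natural SVM margin) and reports the confusion
#' counts and metrics at each threshold, with samples scoring at or above
#' the threshold called positive. The accuracy-maximizing threshold and
#' the most balanced threshold (minimal |Sn - Sp|) are attached as
#' attributes; ties go to the lower threshold.
#'
#' @param scores Numeric decision values.
#' @param labels 0/1 truth labels.
#' @param grid Optional numeric vector of thresholds.
#' @return A tibble of class `ahtpep_threshold_scan` with columns
#'   `threshold`, `tp`, `fp`, `tn`, `fn`, `sn`, `sp`, `acc`, `mcc`.
#' @export
threshold_scan <- function(scores, labels, grid = NULL) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (dplyr::n_distinct(labels) < 2) {
    abort("Both classes must be present.", class = "ahtpep_error_single_class")
  }
  if (is.null(grid)) {
    grid <- sort(unique(c(0, seq(floor(min(scores) * 10) / 10 - 0.1,
                                 ceiling(max(scores) * 10) / 10 + 0.1,
                                 by = 0.1))))
  }
  rows <- purrr::map(grid, function(th) {
    pos <- scores >= th
    tibble::tibble(threshold = th,
                   tp = sum(pos & labels == 1), fp = sum(pos & labels == 0),
                   tn = sum(!pos & labels == 0), fn = sum(!pos & labels == 1))
  })
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::bind_cols(tab, classification_metrics(tab$tp, tab$fp, tab$tn, tab$fn))
  best_acc <- tab$threshold[which.max(tab$acc)]
  balanced <- tab$threshold[which.min(abs(tab$sn - tab$sp))]
  structure(tibble::new_tibble(tab, class = "ahtpep_threshold_scan"),
            best_acc_threshold = best_acc, balanced_threshold = balanced)
}

#' Bundle per-category models and route peptides to them
#'
#' A bundle maps length categories to trained models, mirroring the
#' platform's length-stratified design: a peptide is categorized by length
#' and scored by the category's model -- predicted pIC50 (with the
#' back-converted IC50 in micromolar) for di/tripeptides, a decision score
#' and AHT/non-AHT call for everything longer.
#'
#' @param ... Named `ahtpep_model` objects (names are categories), or
#'   models carrying their `category` field.
#' @return An `ahtpep_bundle`.
#' @export
aht_bundle <- function(...) {
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !inherits(models[[1]], "ahtpep_model")) {
    models <- models[[1]]
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, function(m) m$category %||% "", character(1))
  }
  stopifnot(all(names(models) %in% length_categories()),
            all(vapply(models, inherits, logical(1), "ahtpep_model")))
  structure(models, class = "ahtpep_bundle")
}

#' @export
print.ahtpep_bundle <- function(x, ...) {
  cat(sprintf("<ahtpep model bundle: %s>\n", paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @rdname aht_bundle
#' @param data Data frame with a `sequence` column, or a character vector
#'   of valid peptides.
#' @param bundle An `ahtpep_bundle` covering the peptides' categories.
#' @return `route_and_predict()`: one row per peptide with `sequence`,
#'   `length`, `category`, `task` and the category model's outputs
#'   (`pic50`/`ic50_uM` or `score`/`call`).
#' @export
route_and_predict <- function(data, bundle) {
  stopifnot(inherits(bundle, "ahtpep_bundle"))
  data <- as_sequence_tbl(data)
  data$length <- nchar(data$sequence)
  data$category <- categorize_length(data$length)
  data$task <- category_task(data$category)
  missing <- setdiff(unique(data$category), names(bundle))
  if (length(missing) > 0) {
    abort(sprintf("No model in bundle for category(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ahtpep_error_missing_model")
  }
  data$..order <- seq_len(nrow(data))
  out <- data %>%
    dplyr::group_by(.data$category) %>%
    dplyr::group_modify(function(g, key) {
      pred <- stats::predict(bundle[[key$category[1]]], g)
      dplyr::bind_cols(g, pred)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$..order) %>%
    dplyr::select(-"..order")
  tibble::as_tibble(out)
}
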