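# broom-style accessors and ggplot2 autoplot methods for fitted objects
# and evaluation reports.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained model
#'
#' @param x An `ahtpep_model`.
#' @param ... Unused.
#' @return One row per feature with the model's task, category and
#'   hyperparameters.
#' @export
tidy.ahtpep_model <- function(x, ...) {
  tibble::tibble(
    feature = x$features, task = x$task,
    category = x$category %||% NA_character_,
    cost = x$hyper$cost, gamma = x$hyper$gamma,
    epsilon = if (x$task == "regression") x$hyper$epsilon else NA_real_
  )
}

#' @rdname tidy.ahtpep_model
#' @export
glance.ahtpep_model <- function(x, ...) {
  tibble::tibble(
    task = x$task, n = x$fingerprint$n, n_features = length(x$features),
    n_support_vectors = nrow(x$fit$SV),
    threshold = if (x$task == "classification") x$threshold else NA_real_,
    seed = x$fingerprint$seed, dataset_hash = x$fingerprint$dataset_hash
  )
}

#' Tidy a LOOCV evaluation report
#'
#' @param x An `ahtpep_eval`.
#' @param ... Unused.
#' @return `tidy()`: the per-sample held-out predictions; `glance()`: the
#'   pooled metrics in one row (R/RMSE, or Sn/Sp/Acc/MCC at threshold 0).
#' @export
tidy.ahtpep_eval <- function(x, ...) x$predictions

#' @rdname tidy.ahtpep_eval
#' @export
glance.ahtpep_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(task = x$task, n = x$n), x$metrics)
}

#' Plot a LOOCV evaluation report
#'
#' Regression reports draw observed vs held-out predicted pIC50 with the
#' identity line; classification reports draw the threshold-wise Sn, Sp
#' and Acc curves.
#'
#' @param object An `ahtpep_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ahtpep_eval <- function(object, ...) {
  if (object$task == "regression") {
    ggplot2::ggplot(object$predictions,
                    ggplot2::aes(x = .data$truth, y = .data$prediction)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "observed pIC50", y = "LOOCV-predicted pIC50",
                    title = sprintf("LOOCV regression (n = %d): R = %.3f, RMSE = %.3f",
                                    object$n, object$metrics$r,
                                    object$metrics$rmse)) +
      ggplot2::theme_minimal()
  } else {
    autoplot.ahtpep_threshold_scan(object$threshold_table)
  }
}

#' Plot a threshold scan
#'
#' @param object An `ahtpep_threshold_scan` tibble.
#' @param ... Unused.
#' @return A ggplot of Sn, Sp and Acc (percent) against the decision
#'   threshold.
#' @export
autoplot.ahtpep_threshold_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("threshold", "sn", "sp", "acc")],
    cols = c("sn", "sp", "acc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_acc_threshold"),
                        linetype = 3) +
    ggplot2::labs(x = "decision threshold", y = "percent",
                  colour = NULL,
                  title = "Threshold-wise classification performance") +
    ggplot2::theme_minimal()
}

#' Plot residue composition profiles
#'
#' Side-by-side percent composition of one or more built-in (or
#' user-supplied) profiles, highlighting the residue bias that separates
#' antihypertensive classes from background.
#'
#' @param profiles Character vector of profile ids (see
#'   [composition_profile()]), or a tibble shaped like
#'   [builtin_profiles()].
#' @return A ggplot object.
#' @export
plot_composition <- function(profiles = c("medium", "non_aht")) {
  tab <- if (is.data.frame(profiles)) profiles else {
    builtin_profiles()[c("residue", profiles)]
  }
  long <- tidyr::pivot_longer(tab, cols = -"residue",
                              names_to = "profile", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue, y = .data$percent,
                                     fill = .data$profile)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "composition (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
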