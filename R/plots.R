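# ggplot2 surfaces for the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_boxplot geom_point
#'   geom_histogram labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot the training history of a fitted corrector
#'
#' Train and validation MAE per epoch, with the restored best epoch marked.
#'
#' @param object An `hr_model` with a training history.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_model <- function(object, ...) {
  if (is.null(object$history)) {
    abort("This model carries no training history (reloaded from weights?).",
          class = "frugalhr_domain_error")
  }
  h <- tidyr::pivot_longer(
    object$history[c("epoch", "train_mae", "val_mae")],
    cols = c("train_mae", "val_mae"),
    names_to = "set", values_to = "mae_bpm")
  h$set <- ifelse(h$set == "train_mae", "train", "validation")
  ggplot(h, aes(x = .data$epoch, y = .data$mae_bpm, colour = .data$set)) +
    geom_line() +
    geom_point(data = h[h$epoch == object$best_epoch, ]) +
    labs(x = "epoch", y = "MAE (BPM)", colour = NULL,
         title = "Training history (point: restored best epoch)") +
    theme_minimal()
}

#' Plot an evaluation report as error-distribution boxplots
#'
#' One box per method over the signed errors (prediction minus reference),
#' with 1.5-IQR whiskers.
#'
#' @param object An `hr_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_eval_report <- function(object, ...) {
  ggplot(object$errors, aes(x = .data$method, y = .data$error)) +
    geom_boxplot(outlier.alpha = 0.4) +
    labs(x = NULL, y = "error (BPM)",
         title = sprintf("Error distributions (%d evaluation points)", object$n)) +
    theme_minimal()
}

#' Plot a frugality curve
#'
#' Score against the frugality-importance coefficient w; lower is better.
#'
#' @param object An `hr_frugality_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_frugality_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$w, y = .data$score)) +
    geom_line() +
    labs(x = "w (importance of frugality)", y = "frugality score",
         title = "Frugality curve (lower is better)") +
    theme_minimal()
}

#' Plot tuning results as MAE histograms
#'
#' Histograms of the aggregated train and validation MAE across all tuned
#' architectures, showing how the candidate population is distributed.
#'
#' @param object An `hr_tuning_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_tuning_results <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("train_mae", "val_mae")],
    cols = dplyr::everything(),
    names_to = "set", values_to = "mae_bpm")
  long$set <- ifelse(long$set == "train_mae", "train", "validation")
  ggplot(long, aes(x = .data$mae_bpm)) +
    geom_histogram(bins = 30) +
    facet_wrap(~set, ncol = 1) +
    labs(x = "aggregated MAE (BPM)", y = "architectures",
         title = "Grid-search MAE distributions") +
    theme_minimal()
}
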