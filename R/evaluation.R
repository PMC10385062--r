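# Evaluation metrics, baselines and the frugality score.

#' Mean absolute and mean squared error
#'
#' @param y Observed values (reference heart rates, BPM).
#' @param y_hat Predictions, same length.
#' @return `mae()`: mean of `|y - y_hat|` (BPM); `mse()`: mean of
#'   `(y - y_hat)^2` (BPM^2).
#' @export
mae <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1) {
    abort("`y` and `y_hat` must have equal, positive length.",
          class = "frugalhr_shape_error")
  }
  mean(abs(y - y_hat))
}

#' @rdname mae
#' @export
mse <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1) {
    abort("`y` and `y_hat` must have equal, positive length.",
          class = "frugalhr_shape_error")
  }
  mean((y - y_hat)^2)
}

#' Moving-average baseline
#'
#' The simple smoothing baseline: element i is the mean of the last
#' `window` readings up to and including i, with a partial window at the
#' start of the sequence. Apply per contiguous segment.
#'
#' @param x Numeric sequence of device heart-rate readings.
#' @param window Window length (default 5 readings).
#' @return Smoothed sequence, same length as `x`.
#' @export
moving_average_baseline <- function(x, window = 5) {
  if (length(x) < 1) {
    abort("`x` must be non-empty.", class = "frugalhr_empty_input_error")
  }
  window <- check_count(window, "window")
  vapply(seq_along(x), function(i) {
    mean(x[max(1L, i - window + 1L):i])
  }, numeric(1))
}

#' Evaluate the model against the raw and moving-average baselines
#'
#' Computes MAE and MSE against the reference heart rate for three methods
#' on the same evaluation points: the raw device reading, the
#' moving average of the last `ma_window` device readings (computed within
#' each contiguous segment of the full aligned table, then restricted to
#' the evaluation rows), and the model's corrected output. Also summarizes
#' each method's signed error distribution by quartiles and 1.5-IQR
#' box-plot outliers.
#'
#' @param rows Feature rows to evaluate on (typically the test block of
#'   [split_rows()]), carrying `hr_device`, `target` and the feature
#'   columns.
#' @param model A trained `hr_model`.
#' @param dataset The aligned table the rows were built from (needed to
#'   form the moving average over the raw reading history).
#' @param ma_window Moving-average window in readings.
#' @return An object of class `hr_eval_report`: `summary` tibble (one row
#'   per method with `mae`, `mse`, error quartiles, `n_outliers`), long
#'   `errors` tibble (`method`, `error`), list `outliers`, and `n`.
#' @export
evaluate_methods <- function(rows, model, dataset, ma_window = 5) {
  if (nrow(rows) == 0) {
    abort("Evaluation set is empty.", class = "frugalhr_empty_input_error")
  }
  y <- rows$target
  preds <- list(
    raw = rows$hr_device,
    moving_average = {
      ma_tbl <- dplyr::group_by(dataset, .data$participant_id)
      ma_tbl <- dplyr::mutate(ma_tbl, .record = dplyr::row_number())
      ma_tbl <- dplyr::group_by(ma_tbl, .data$participant_id, .data$segment_id)
      ma_tbl <- dplyr::mutate(
        ma_tbl, .ma = moving_average_baseline(.data$hr_device, ma_window))
      ma_tbl <- dplyr::ungroup(ma_tbl)
      joined <- dplyr::left_join(
        rows[c("participant_id", ".record")],
        ma_tbl[c("participant_id", ".record", ".ma")],
        by = c("participant_id", ".record"))
      joined$.ma
    },
    model = predict(model, rows)
  )

  summarize_errors <- function(err) {
    q <- unname(stats::quantile(err, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    out <- err[err < q[1] - 1.5 * iqr | err > q[3] + 1.5 * iqr]
    list(q1 = q[1], median = q[2], q3 = q[3], outliers = out)
  }

  methods <- names(preds)
  summaries <- lapply(methods, function(mth) {
    err <- preds[[mth]] - y
    s <- summarize_errors(err)
    tibble(method = mth, mae = mae(y, preds[[mth]]),
           mse = mse(y, preds[[mth]]),
           q1 = s$q1, median = s$median, q3 = s$q3,
           n_outliers = length(s$outliers))
  })
  errors <- dplyr::bind_rows(lapply(methods, function(mth) {
    tibble(method = mth, error = preds[[mth]] - y)
  }))
  errors$method <- factor(errors$method, levels = methods)
  outliers <- lapply(methods, function(mth) {
    summarize_errors(preds[[mth]] - y)$outliers
  })
  names(outliers) <- methods

  structure(
    list(summary = dplyr::bind_rows(summaries), errors = errors,
         outliers = outliers, n = length(y)),
    class = "hr_eval_report"
  )
}

#' @export
print.hr_eval_report <- function(x, ...) {
  cat(sprintf("<hr_eval_report> %d evaluation points\n", x$n))
  print(x$summary)
  invisible(x)
}

#' Render an evaluation report as a Markdown table
#'
#' @param report An `hr_eval_report`.
#' @return Character vector of Markdown lines (Method | MAE | MSE).
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "hr_eval_report"))
  labels <- c(raw = "Raw measurement", moving_average = "Moving average",
              model = "Proposed method")
  c("| Method | MAE | MSE |",
    "|---|---|---|",
    sprintf("| %s | %.2f | %.2f |",
            labels[report$summary$method],
            report$summary$mae, report$summary$mse))
}

#' Frugality score and curve
#'
#' Scores a model by trading its test error against its resource footprint:
#' with the default `"difference"` reading,
#' `score = mae_test - w / (1 + 1 / (u_ram * t_cpu))`,
#' where `w` in \[0, 1\] expresses how much resource frugality matters (0:
#' resources are free, the score is just the test MAE; 1: extremely scarce
#' resources). Lower scores are better. Because the resource term is
#' subtracted, a method only improves its score through a small
#' memory-times-time product; for the footprint of this corrector (880
#' bytes, 0.184 ms) the penalty term is close to its limit of `w`. The
#' `"power"` variant reads the same symbols as an exponent,
#' `mae_test ^ (-w / (1 + 1 / (u_ram * t_cpu)))`, and is provided for
#' comparison only.
#'
#' @param mae_test Test mean absolute error (BPM).
#' @param u_ram Method-attributable memory use in bytes (default: the
#'   880 B measured for the deployed corrector).
#' @param t_cpu Per-inference compute time in milliseconds (default: the
#'   0.184 ms measured on the target device).
#' @param w Importance of resource frugality, in \[0, 1\].
#' @param variant Score reading; `"difference"` is the adopted default.
#' @return `frugality_score()`: the scalar score. `frugality_curve()`: a
#'   tibble of class `hr_frugality_curve` with columns `w`, `score`.
#' @export
frugality_score <- function(mae_test, u_ram = 880, t_cpu = 0.184, w = 1,
                            variant = c("difference", "power")) {
  variant <- match.arg(variant)
  check_scalar_number(mae_test, "mae_test", min = 0)
  check_scalar_number(u_ram, "u_ram", min = 0, strict = TRUE)
  check_scalar_number(t_cpu, "t_cpu", min = 0, strict = TRUE)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    abort("`w` must lie in [0, 1].", class = "frugalhr_domain_error")
  }
  penalty <- w / (1 + 1 / (u_ram * t_cpu))
  switch(variant,
         difference = mae_test - penalty,
         power = mae_test^(-penalty))
}

#' @rdname frugality_score
#' @param n Number of evenly spaced `w` values over \[0, 1\].
#' @export
frugality_curve <- function(mae_test, u_ram = 880, t_cpu = 0.184, n = 21,
                            variant = c("difference", "power")) {
  variant <- match.arg(variant)
  n <- check_count(n, "n", min = 2L)
  w <- seq(0, 1, length.out = n)
  out <- tibble(w = w,
                score = frugality_score(mae_test, u_ram, t_cpu, w,
                                        variant = variant))
  class(out) <- c("hr_frugality_curve", class(out))
  out
}
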