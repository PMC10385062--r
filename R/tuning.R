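# Architecture grid search.
#
# The window sizes (m, k) and the layer layout are tuned jointly by
# exhaustive grid search. Every candidate is trained several times from
# different random initializations and the repeat MAEs are aggregated to
# reduce initialization variance; the final model is then chosen among the
# near-best candidates by parameter count, since on the target device size
# matters as much as accuracy.

#' Hyperparameter grid for architecture tuning
#'
#' Defaults are the ranges the corrector was tuned over: heart-rate window
#' in \{1, 3, 5, 7\}, acceleration window in \{1, 3, 5\}, 1-6 units in the
#' first hidden layer, 0-2 additional hidden layers with 1-4 units shared
#' by every additional layer, five repeats per candidate. The default grid
#' enumerates to 648 unique architectures.
#'
#' @param hr_window Choices for the heart-rate window size m.
#' @param accel_window Choices for the acceleration window count k.
#' @param first_hidden_units Choices for the first hidden layer width.
#' @param additional_hidden_layers Choices for the number of additional
#'   hidden layers.
#' @param additional_hidden_units Choices for the (shared) width of the
#'   additional hidden layers; irrelevant when a candidate has none.
#' @param repeats Training repeats per candidate.
#' @return A list of class `hr_tuning_grid`.
#' @export
tuning_grid <- function(hr_window = c(1, 3, 5, 7), accel_window = c(1, 3, 5),
                        first_hidden_units = 1:6,
                        additional_hidden_layers = 0:2,
                        additional_hidden_units = 1:4, repeats = 5) {
  repeats <- check_count(repeats, "repeats")
  structure(
    list(hr_window = as.integer(hr_window),
         accel_window = as.integer(accel_window),
         first_hidden_units = as.integer(first_hidden_units),
         additional_hidden_layers = as.integer(additional_hidden_layers),
         additional_hidden_units = as.integer(additional_hidden_units),
         repeats = repeats),
    class = "hr_tuning_grid"
  )
}

#' Enumerate the unique architectures of a tuning grid
#'
#' Expands every (m, k, first hidden units, additional layers, additional
#' units) combination exactly once. Because the additional-units choice is
#' meaningless for candidates with zero additional layers, those rows are
#' collapsed: a grid with u unit choices and layer-count choices \{0, 1, 2\}
#' yields `|m| * |k| * |first| * (1 + u + u)` specs — 648 for the default.
#'
#' @param grid An [tuning_grid()].
#' @return A tibble with one row per unique spec: `m`, `k`, `first_units`,
#'   `extra_layers`, `extra_units` (`NA` when `extra_layers == 0`),
#'   `n_parameters` and a list-column `spec` of [model_spec()] objects.
#' @export
enumerate_grid <- function(grid = tuning_grid()) {
  stopifnot(inherits(grid, "hr_tuning_grid"))
  combos <- tidyr::expand_grid(
    m = grid$hr_window, k = grid$accel_window,
    first_units = grid$first_hidden_units,
    extra_layers = grid$additional_hidden_layers,
    extra_units = grid$additional_hidden_units
  )
  combos$extra_units[combos$extra_layers == 0L] <- NA_integer_
  combos <- dplyr::distinct(combos)
  combos$spec <- purrr::pmap(
    combos[c("m", "k", "first_units", "extra_layers", "extra_units")],
    function(m, k, first_units, extra_layers, extra_units) {
      hidden <- c(first_units,
                  if (extra_layers > 0L) rep(extra_units, extra_layers))
      model_spec(m, k, hidden)
    })
  combos$n_parameters <- vapply(combos$spec, count_parameters, integer(1))
  combos
}

#' Run the architecture grid search
#'
#' Trains every candidate `repeats` times on the train/validation blocks of
#' a leakage-free split, with repeats differing only in the initialization
#' and shuffling seed (`config$seed`, `config$seed + 1`, ...). Feature rows
#' and normalization are rebuilt per unique (m, k); the test block of the
#' split is never touched. A diverged repeat is recorded as missing and the
#' aggregate is taken over the remaining repeats with `n_failed` flagged.
#'
#' @param specs Tibble from [enumerate_grid()] (or a subset of its rows).
#' @param dataset Aligned session table; split internally with
#'   `config$split`.
#' @param config A [train_config()].
#' @param repeats Training repeats per candidate.
#' @param aggregate `"mean"` (default) or `"min"` over repeats.
#' @param include_current Passed to [build_feature_rows()].
#' @return A tibble of class `hr_tuning_results`, sorted by aggregated
#'   validation MAE: spec columns, list-columns `repeat_train_mae` /
#'   `repeat_val_mae`, aggregates `train_mae` / `val_mae`, `n_failed`.
#' @export
run_grid_search <- function(specs, dataset, config = train_config(),
                            repeats = 5, aggregate = c("mean", "min"),
                            include_current = TRUE) {
  aggregate <- match.arg(aggregate)
  repeats <- check_count(repeats, "repeats")
  agg_fun <- if (aggregate == "mean") mean else min

  # One split + normalization per unique window configuration.
  window_cache <- new.env(parent = emptyenv())
  get_windows <- function(m, k) {
    key <- paste(m, k, sep = "_")
    if (is.null(window_cache[[key]])) {
      rows <- build_feature_rows(dataset, m, k,
                                 include_current = include_current)
      sp <- split_rows(rows, config$split)
      window_cache[[key]] <- list(train = sp$train, validation = sp$validation,
                                  norm = fit_normalization(sp$train))
    }
    window_cache[[key]]
  }

  res <- purrr::pmap(
    specs[c("spec")],
    function(spec) {
      w <- get_windows(spec$m, spec$k)
      tr_mae <- val_mae <- rep(NA_real_, repeats)
      for (r in seq_len(repeats)) {
        cfg <- config
        cfg$seed <- config$seed + r - 1L
        fit <- tryCatch(
          train_model(spec, w$train, w$validation, cfg, normalization = w$norm),
          frugalhr_divergence_error = function(e) NULL
        )
        if (!is.null(fit)) {
          h <- fit$history[fit$best_epoch, ]
          tr_mae[r] <- h$train_mae
          val_mae[r] <- h$val_mae
        }
      }
      ok <- !is.na(val_mae)
      tibble(
        repeat_train_mae = list(tr_mae), repeat_val_mae = list(val_mae),
        train_mae = if (any(ok)) agg_fun(tr_mae[ok]) else NA_real_,
        val_mae = if (any(ok)) agg_fun(val_mae[ok]) else NA_real_,
        n_failed = sum(!ok)
      )
    })

  out <- dplyr::bind_cols(specs, dplyr::bind_rows(res))
  out <- dplyr::arrange(out, .data$val_mae)
  class(out) <- c("hr_tuning_results", class(out))
  out
}

#' Select the final architecture by size among the near-best
#'
#' Among candidates whose aggregated validation MAE is within
#' `mae_tolerance` of the best, returns the spec with the fewest
#' parameters; remaining ties break to fewer layers, then smaller m, then
#' smaller k.
#'
#' @param results An `hr_tuning_results` tibble.
#' @param mae_tolerance Validation-MAE slack (BPM) defining the near-best
#'   set; 0 selects the exact argmin.
#' @return The selected [model_spec()].
#' @export
select_final <- function(results, mae_tolerance = 0.1) {
  if (nrow(results) == 0) {
    abort("No tuning results to select from.",
          class = "frugalhr_empty_input_error")
  }
  check_scalar_number(mae_tolerance, "mae_tolerance", min = 0)
  ok <- !is.na(results$val_mae)
  best <- min(results$val_mae[ok])
  cand <- results[ok & results$val_mae <= best + mae_tolerance, ]
  n_layers <- vapply(cand$spec, function(s) length(s$hidden_units), integer(1))
  ord <- order(cand$n_parameters, n_layers, cand$m, cand$k)
  cand$spec[[ord[1]]]
}

#' Write tuning results as CSV
#'
#' Flattens the per-repeat list-columns to semicolon-joined strings.
#'
#' @param results An `hr_tuning_results` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_results <- function(results, path) {
  flat <- dplyr::select(as_tibble(results), -"spec")
  flat$repeat_train_mae <- vapply(results$repeat_train_mae, function(v) {
    paste(sprintf("%.6g", v), collapse = ";")
  }, character(1))
  flat$repeat_val_mae <- vapply(results$repeat_val_mae, function(v) {
    paste(sprintf("%.6g", v), collapse = ";")
  }, character(1))
  readr::write_csv(flat, path)
  invisible(path)
}
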