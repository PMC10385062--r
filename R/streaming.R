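# Streaming (on-device) inference emulation.
#
# Mirrors the firmware implementation of the corrector: acceleration
# magnitudes are kept in an insertion-sorted buffer for the current
# inter-reading window; when a heart-rate reading arrives the buffer is
# summarized by indexing into the sorted values and cleared; the m most
# recent raw readings and the k most recent summary triples live in
# constant-size rolling buffers; normalization multiplies by precomputed
# inverted standard deviations so the hot path contains no division.
# Until the rolling buffers are full (warm-up) the raw reading is passed
# through unchanged, flagged as uncorrected.

#' Create a streaming inference state
#'
#' @param model An `hr_model` with bundled normalization statistics.
#' @param accel_capacity Maximum acceleration samples per inter-reading
#'   window; exceeding it is an error (the device's buffer is fixed).
#' @return A mutable state object of class `hr_stream` (an environment);
#'   feed it with [stream_push_accel()] and [stream_push_hr()].
#' @export
stream_init <- function(model, accel_capacity = 256) {
  stopifnot(inherits(model, "hr_model"))
  accel_capacity <- check_count(accel_capacity, "accel_capacity")
  state <- new.env(parent = emptyenv())
  state$model <- model
  state$m <- model$spec$m
  state$k <- model$spec$k
  state$norm_mean <- unname(model$norm_stats$mean)
  state$norm_inv_std <- unname(model$norm_stats$inv_std)
  state$capacity <- accel_capacity
  state$accel_buf <- numeric(0)
  state$hr_buf <- numeric(0)
  state$summ_buf <- matrix(numeric(0), ncol = 3)
  state$prev_summary <- NULL
  state$n_seen <- 0L
  class(state) <- "hr_stream"
  state
}

#' Push one acceleration magnitude into the stream state
#'
#' Inserts the value at its sorted position (the insertion-sort strategy of
#' the device: O(n) insert, no sorting pass afterwards).
#'
#' @param state An `hr_stream`.
#' @param magnitude Finite acceleration magnitude.
#' @return `state`, invisibly (modified in place).
#' @export
stream_push_accel <- function(state, magnitude) {
  if (!is.finite(magnitude)) {
    abort("Acceleration magnitude must be finite.",
          class = "frugalhr_domain_error")
  }
  if (length(state$accel_buf) >= state$capacity) {
    abort(sprintf("Acceleration buffer capacity (%d) exceeded within one inter-reading window.",
                  state$capacity),
          class = "frugalhr_overflow_error")
  }
  pos <- findInterval(magnitude, state$accel_buf)
  state$accel_buf <- append(state$accel_buf, magnitude, after = pos)
  invisible(state)
}

#' Push one heart-rate reading and run inference if warm
#'
#' Summarizes and clears the acceleration buffer (reusing the previous
#' window's summary, flagged, if no acceleration arrived), rotates the
#' rolling heart-rate and summary buffers, and — once at least m readings
#' and k summaries have accumulated — normalizes the feature vector by
#' multiplying with the precomputed inverted standard deviations and
#' returns the model output. During warm-up the raw reading is returned,
#' flagged as uncorrected.
#'
#' @param state An `hr_stream`.
#' @param bpm Finite raw heart-rate reading.
#' @return List with `value` (corrected or raw BPM), `corrected` (logical)
#'   and `reused_summary` (logical: the window had no acceleration sample).
#' @export
stream_push_hr <- function(state, bpm) {
  if (!is.finite(bpm)) {
    abort("Heart-rate reading must be finite.",
          class = "frugalhr_domain_error")
  }
  reused <- FALSE
  if (length(state$accel_buf) > 0) {
    s <- sorted_window_summary3(state$accel_buf)
  } else if (!is.null(state$prev_summary)) {
    s <- state$prev_summary
    reused <- TRUE
  } else {
    s <- NULL
  }
  state$accel_buf <- numeric(0)
  if (!is.null(s)) {
    state$prev_summary <- s
    state$summ_buf <- rbind(state$summ_buf, s)
    if (nrow(state$summ_buf) > state$k) {
      state$summ_buf <- state$summ_buf[-1, , drop = FALSE]
    }
  }
  state$hr_buf <- c(state$hr_buf, bpm)
  if (length(state$hr_buf) > state$m) {
    state$hr_buf <- state$hr_buf[-1]
  }
  state$n_seen <- state$n_seen + 1L

  warm <- length(state$hr_buf) == state$m && nrow(state$summ_buf) == state$k
  if (!warm) {
    return(list(value = bpm, corrected = FALSE, reused_summary = reused))
  }
  v <- c(state$hr_buf, state$summ_buf[, 1], state$summ_buf[, 2],
         state$summ_buf[, 3])
  vn <- (v - state$norm_mean) * state$norm_inv_std
  list(value = nn_forward(state$model, vn), corrected = TRUE,
       reused_summary = reused)
}

# Summary of an already-sorted buffer: median, max, nearest-rank IQR.
# Indexing only (plus one multiplication for the even-length median), as on
# the device.
sorted_window_summary3 <- function(s) {
  n <- length(s)
  med <- if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) * 0.5
  q1 <- s[(0.25 * (n - 1)) %/% 1 + 1]
  q3 <- s[(0.75 * (n - 1)) %/% 1 + 1]
  c(med, s[n], q3 - q1)
}

#' Replay an aligned session through the streaming emulation
#'
#' Feeds each record's acceleration window and raw reading through the
#' stream state, resetting the state at every contiguity segment boundary
#' (a segment break means the device stream was interrupted, so stale
#' buffers must not leak across it). Post-warm-up outputs equal the batch
#' pipeline's predictions.
#'
#' @param dataset Aligned table from [align_streams()].
#' @param model A trained `hr_model`.
#' @param accel_capacity Per-window acceleration buffer capacity.
#' @return Tibble with one row per device reading: `participant_id`,
#'   `segment_id`, `t`, `raw`, `corrected`, `warm`, `reused_summary`.
#' @export
stream_replay <- function(dataset, model, accel_capacity = 256) {
  groups <- dplyr::group_split(dataset, .data$participant_id,
                               .data$segment_id)
  out <- lapply(groups, function(d) {
    state <- stream_init(model, accel_capacity)
    res <- lapply(seq_len(nrow(d)), function(i) {
      for (a in d$accel_mags[[i]]) stream_push_accel(state, a)
      r <- stream_push_hr(state, d$hr_device[i])
      tibble(participant_id = d$participant_id[i],
             segment_id = d$segment_id[i],
             t = d$t_device[i], raw = d$hr_device[i],
             corrected = r$value, warm = r$corrected,
             reused_summary = r$reused_summary)
    })
    dplyr::bind_rows(res)
  })
  dplyr::bind_rows(out)
}

#' Write a streaming replay as a per-event CSV
#'
#' @param replay Tibble from [stream_replay()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_replay <- function(replay, path) {
  readr::write_csv(replay, path)
  invisible(path)
}
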