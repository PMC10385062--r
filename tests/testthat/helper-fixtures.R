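# Shared fixtures, all generated in code.

# Hand-built aligned table: one participant, two segments, known windows.
tiny_aligned <- function() {
  tibble::tibble(
    participant_id = "p1",
    segment_id = c(1L, 1L, 1L, 2L, 2L),
    t_device = c(12, 24, 36, 120, 132),
    hr_device = c(80, 82, 84, 90, 92),
    t_ref = c(15, 25, 35, 122, 130),
    hr_ref = c(79, 81, 85, 91, 93),
    accel_mags = list(c(1, 2, 3), c(2, 2), c(1, 5, 3, 4),
                      c(2, 4), c(1))
  )
}

# Aligned table with n contiguous records for one participant; constant
# windows so feature values are predictable.
contiguous_aligned <- function(n, participant_id = "p1", hr = NULL) {
  if (is.null(hr)) hr <- 80 + seq_len(n) %% 7
  tibble::tibble(
    participant_id = participant_id,
    segment_id = 1L,
    t_device = 12 * seq_len(n),
    hr_device = hr,
    t_ref = 12 * seq_len(n) + 1,
    hr_ref = hr - 5,
    accel_mags = lapply(seq_len(n), function(i) c(1, 1 + i %% 3, 2))
  )
}

# Small default-noise synthetic cohort; cached per session lifetime.
cohort_cache <- new.env(parent = emptyenv())
small_cohort_aligned <- function(n_participants = 2, seed_base = 7000) {
  key <- paste0("c", n_participants, "_", seed_base)
  if (is.null(cohort_cache[[key]])) {
    sessions <- lapply(seq_len(n_participants), function(i) {
      simulate_session(seed = seed_base + i,
                       participant_id = paste0("p", i))
    })
    cohort_cache[[key]] <- dplyr::bind_rows(lapply(sessions, function(s) {
      align_streams(s$device_hr, s$ref_hr, s$accel,
                    participant_id = s$participant_id)
    }))
  }
  cohort_cache[[key]]
}

# A model with specified constant weights (for exact-output tests).
constant_model <- function(spec, rows, fill = 0, out_bias = 0) {
  norm <- fit_normalization(rows)
  dims <- c(spec$input_dim, spec$hidden_units, 1L)
  layers <- lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(fill, dims[l], dims[l + 1L]), b = numeric(dims[l + 1L]))
  })
  layers[[length(layers)]]$b[] <- out_bias
  structure(list(spec = spec, layers = layers, norm_stats = norm,
                 config = NULL, history = NULL, best_epoch = NA_integer_,
                 n_train = NA_integer_, n_val = NA_integer_),
            class = "hr_model")
}

# Independent loop-based forward oracle: no matrix ops shared with the
# implementation.
forward_oracle <- function(layers, x) {
  a <- as.numeric(x)
  n_layers <- length(layers)
  for (l in seq_len(n_layers)) {
    W <- layers[[l]]$W
    out <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- layers[[l]]$b[j]
      for (i in seq_len(nrow(W))) s <- s + a[i] * W[i, j]
      out[j] <- if (l < n_layers) max(0, s) else s
    }
    a <- out
  }
  a[1]
}
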