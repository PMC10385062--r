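# Sliding-window feature construction.
#
# Each device heart-rate reading i is described by the m most recent raw
# readings and by k triples (median, maximum, IQR) summarizing the
# acceleration magnitudes of the k most recent inter-reading windows. The
# feature vector is laid out grouped by statistic:
#   <h_1..h_m, a_1^med..a_k^med, a_1^max..a_k^max, a_1^iqr..a_k^iqr>
# with index 1 the oldest, so its length is m + 3k. The window summaries
# are chosen to be computable by one sort plus O(1) indexing, matching what
# the target device can afford.

#' Euclidean acceleration magnitude
#'
#' @param ax,ay,az Acceleration components (device units), vectorized.
#' @return Non-negative magnitudes `sqrt(ax^2 + ay^2 + az^2)`.
#' @export
#' @examples
#' accel_magnitude(3, 4, 0)
accel_magnitude <- function(ax, ay, az) {
  if (any(!is.finite(ax)) || any(!is.finite(ay)) || any(!is.finite(az))) {
    abort("Acceleration components must be finite.",
          class = "frugalhr_domain_error")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

# Sort-and-index summary of one window: c(median, max, nearest-rank IQR).
# Median of an even-length window is the midpoint of the two central
# elements (a single multiplication by 0.5); the IQR uses the zero-based
# nearest-rank positions floor(0.25(n-1)) and floor(0.75(n-1)) so that, as
# on the device, only indexing follows the sort.
window_summary3 <- function(a) {
  n <- length(a)
  s <- sort(a)
  med <- if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) * 0.5
  q1 <- s[(0.25 * (n - 1)) %/% 1 + 1]
  q3 <- s[(0.75 * (n - 1)) %/% 1 + 1]
  c(med, s[n], q3 - q1)
}

#' Summarize an acceleration window
#'
#' Computes the three per-window statistics fed to the model: median,
#' maximum and interquartile range of the magnitudes, using the sort-plus-
#' indexing conventions described in the package vignette (even-length
#' median as midpoint of the central pair; IQR from zero-based nearest-rank
#' quartile positions).
#'
#' @param a Numeric vector of acceleration magnitudes, length >= 1.
#' @return A one-row tibble with `med`, `mx`, `iqr`, `n`.
#' @export
#' @examples
#' summarize_window(c(1, 2, 3, 4, 5))
summarize_window <- function(a) {
  if (length(a) < 1) {
    abort("Acceleration window is empty.", class = "frugalhr_empty_window_error")
  }
  if (any(!is.finite(a))) {
    abort("Acceleration magnitudes must be finite.",
          class = "frugalhr_domain_error")
  }
  v <- window_summary3(a)
  tibble(med = v[1], mx = v[2], iqr = v[3], n = length(a))
}

#' Names of the feature columns for a window configuration
#'
#' @param m Heart-rate window size.
#' @param k Acceleration window count.
#' @return Character vector `h1..hm, amed1..amedk, amax1..amaxk,
#'   aiqr1..aiqrk` in feature-vector order.
#' @export
feature_cols <- function(m, k) {
  m <- check_count(m, "m"); k <- check_count(k, "k")
  c(paste0("h", seq_len(m)),
    paste0("amed", seq_len(k)),
    paste0("amax", seq_len(k)),
    paste0("aiqr", seq_len(k)))
}

#' Build feature rows from an aligned session table
#'
#' Slides the (m, k) windows over each contiguous segment of the aligned
#' table and emits one feature row per device reading with enough history.
#' Windows never cross segment boundaries, so a dropped reading can never
#' leak stale context into a feature vector. With
#' `include_current = TRUE` (default) the current raw reading is the last
#' heart-rate feature `h_m`; with `FALSE` the heart-rate window holds the m
#' strictly previous readings. In both cases the last acceleration summary
#' `a_k` describes the current inter-reading window and the target is the
#' reference heart rate paired with the current reading.
#'
#' Records whose inter-reading window contains no acceleration sample reuse
#' the previous window's summary within the segment; leading records of a
#' segment with no summary available yet yield no rows.
#'
#' @param dataset Aligned tibble from [align_streams()] (or
#'   [read_processed()]).
#' @param m Heart-rate window size (>= 1).
#' @param k Acceleration window count (>= 1).
#' @param include_current Include the current reading in its own
#'   heart-rate window.
#' @return Tibble with metadata columns `participant_id`, `segment_id`,
#'   `t_device`, `hr_device`, `.record`, `.first_record` (per-participant
#'   record indices of the newest and oldest record a row draws on), the
#'   feature columns of [feature_cols()] and `target`.
#' @export
build_feature_rows <- function(dataset, m, k, include_current = TRUE) {
  m <- check_count(m, "m"); k <- check_count(k, "k")
  cols <- feature_cols(m, k)

  dataset <- dplyr::group_by(dataset, .data$participant_id)
  dataset <- dplyr::mutate(dataset, .record = dplyr::row_number())
  dataset <- dplyr::ungroup(dataset)

  per_segment <- function(d) {
    nrec <- nrow(d)
    # Per-record summaries with carry-forward over empty windows.
    summ <- matrix(NA_real_, nrow = nrec, ncol = 3)
    for (i in seq_len(nrec)) {
      a <- d$accel_mags[[i]]
      if (length(a) > 0) {
        summ[i, ] <- window_summary3(a)
      } else if (i > 1 && !anyNA(summ[i - 1, ])) {
        summ[i, ] <- summ[i - 1, ]
      }
    }
    first_i <- if (include_current) max(m, k) else max(m + 1L, k)
    if (nrec < first_i) return(NULL)
    idx <- first_i:nrec
    rows <- lapply(idx, function(i) {
      h_idx <- if (include_current) (i - m + 1L):i else (i - m):(i - 1L)
      s_idx <- (i - k + 1L):i
      if (anyNA(summ[s_idx, ])) return(NULL)
      c(d$hr_device[h_idx], summ[s_idx, 1], summ[s_idx, 2], summ[s_idx, 3])
    })
    ok <- !vapply(rows, is.null, logical(1))
    if (!any(ok)) return(NULL)
    feat <- do.call(rbind, rows[ok])
    colnames(feat) <- cols
    first_rec <- vapply(idx[ok], function(i) {
      min(if (include_current) i - m + 1L else i - m, i - k + 1L)
    }, numeric(1))
    dplyr::bind_cols(
      tibble(participant_id = d$participant_id[idx[ok]],
             segment_id = d$segment_id[idx[ok]],
             t_device = d$t_device[idx[ok]],
             hr_device = d$hr_device[idx[ok]],
             .record = d$.record[idx[ok]],
             .first_record = d$.record[1] + first_rec - 1),
      as_tibble(feat),
      tibble(target = d$hr_ref[idx[ok]])
    )
  }

  groups <- dplyr::group_split(dataset, .data$participant_id, .data$segment_id)
  out <- dplyr::bind_rows(lapply(groups, per_segment))
  if (nrow(out) == 0) {
    warn("No feature rows could be built (segments shorter than the windows).")
  }
  out
}

# Feature matrix in vector order from a rows tibble.
feature_matrix <- function(rows, cols = NULL) {
  if (is.null(cols)) {
    cols <- grep("^(h|amed|amax|aiqr)[0-9]+$", names(rows), value = TRUE)
  }
  as.matrix(rows[cols])
}

#' Fit and apply train-set feature normalization
#'
#' `fit_normalization()` computes the per-feature mean and the
#' *pre-inverted* standard deviation (`inv_std = 1/sd`) from training rows,
#' mirroring the on-device implementation where normalization must use
#' multiplication only. Features with zero training variance get
#' `inv_std = 1` and are flagged. `apply_normalization()` rescales the
#' feature columns as `(x - mean) * inv_std`, leaving targets and metadata
#' untouched.
#'
#' @param rows Feature-row tibble from [build_feature_rows()] (>= 2 rows
#'   for fitting).
#' @return `fit_normalization()`: an object of class `hr_norm_stats` with
#'   `mean`, `inv_std`, `constant` (logical flag per feature) and
#'   `features`. `apply_normalization()`: `rows` with normalized feature
#'   columns.
#' @export
fit_normalization <- function(rows) {
  x <- feature_matrix(rows)
  if (nrow(x) < 2) {
    abort("At least 2 rows are required to fit normalization.",
          class = "frugalhr_insufficient_data_error")
  }
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  constant <- !is.finite(sdev) | sdev <= 0
  inv_std <- ifelse(constant, 1, 1 / sdev)
  structure(list(mean = mu, inv_std = inv_std, constant = constant,
                 features = colnames(x)),
            class = "hr_norm_stats")
}

#' @rdname fit_normalization
#' @param stats An `hr_norm_stats` object.
#' @export
apply_normalization <- function(rows, stats) {
  stopifnot(inherits(stats, "hr_norm_stats"))
  x <- feature_matrix(rows, stats$features)
  xn <- sweep(x, 2, stats$mean, "-")
  xn <- sweep(xn, 2, stats$inv_std, "*")
  rows[stats$features] <- as_tibble(xn)
  attr(rows, "normalized") <- TRUE
  rows
}

#' @rdname fit_normalization
#' @export
invert_normalization <- function(rows, stats) {
  stopifnot(inherits(stats, "hr_norm_stats"))
  x <- feature_matrix(rows, stats$features)
  xr <- sweep(x, 2, stats$inv_std, "/")
  xr <- sweep(xr, 2, stats$mean, "+")
  rows[stats$features] <- as_tibble(xr)
  attr(rows, "normalized") <- FALSE
  rows
}
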