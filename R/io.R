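# Raw-stream reading and time alignment.
#
# A session consists of three raw streams: wrist-device heart rate (~12 s
# cadence), reference ECG heart rate (15 s cadence) and three-axis wrist
# acceleration (~4 Hz). Alignment takes the device readings as the primary
# series, pairs each with its nearest-in-time reference reading, and
# attaches the acceleration magnitudes recorded since the previous retained
# device reading.

STREAM_FILES <- c(device_hr = "device_hr", ref_hr = "ref_hr", accel = "accel")

default_stream_columns <- function() {
  list(device_hr = c(t = "t", bpm = "bpm"),
       ref_hr = c(t = "t", bpm = "bpm"),
       accel = c(t = "t", ax = "ax", ay = "ay", az = "az"))
}

# Converts a timestamp column to numeric seconds. Absolute datetimes
# (POSIXct or parseable strings) are flagged so the caller can re-base the
# session onto a common relative axis.
parse_time_column <- function(x, stream) {
  if (is.numeric(x)) return(list(t = as.numeric(x), absolute = FALSE))
  if (inherits(x, "POSIXt")) return(list(t = as.numeric(x), absolute = TRUE))
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    parse_one <- function(s) {
      suppressWarnings(tryCatch(as.numeric(as.POSIXct(s, tz = "UTC")),
                                error = function(e) NA_real_))
    }
    parsed <- parse_one(x)
    if (length(parsed) != length(x)) {   # vector parse aborted entirely
      parsed <- vapply(x, parse_one, numeric(1), USE.NAMES = FALSE)
    }
    bad <- which(is.na(parsed) & !is.na(x))
    if (length(bad) > 0) {
      abort(sprintf("Unparseable timestamp in %s stream at row %d.",
                    stream, bad[1]),
            class = "frugalhr_format_error")
    }
    return(list(t = parsed, absolute = TRUE))
  }
  abort(sprintf("Timestamp column of %s stream has unsupported type.", stream),
        class = "frugalhr_format_error")
}

read_one_stream <- function(path, stream, format, columns) {
  ext <- if (format == "feather") "feather" else "csv"
  file <- file.path(path, paste0(STREAM_FILES[[stream]], ".", ext))
  if (!file.exists(file)) {
    abort(sprintf("Stream file not found: %s", file),
          class = "frugalhr_io_error")
  }
  raw <- if (format == "feather") {
    as_tibble(arrow::read_feather(file))
  } else {
    readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  }
  map <- columns[[stream]]
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Stream %s is missing column(s): %s", stream,
                  paste(missing_cols, collapse = ", ")),
          class = "frugalhr_schema_error")
  }
  out <- raw[unname(map)]
  names(out) <- names(map)
  parsed <- parse_time_column(out$t, stream)
  out$t <- parsed$t
  list(data = as_tibble(out), absolute = parsed$absolute)
}

#' Read the three raw streams of a session
#'
#' Reads `device_hr`, `ref_hr` and `accel` tables (Feather or CSV) from a
#' directory, maps columns via `columns`, converts absolute datetimes to
#' session-relative seconds (subtracting the earliest timestamp seen across
#' all three streams), sorts each stream by time and drops rows with
#' non-finite values, reporting the per-stream drop counts.
#'
#' @param path Directory holding `device_hr.*`, `ref_hr.*`, `accel.*`.
#' @param format `"feather"` or `"csv"`.
#' @param columns Column-name mapping per stream, as produced by the
#'   default: a list with entries `device_hr = c(t = ..., bpm = ...)`,
#'   `ref_hr = c(t = ..., bpm = ...)`,
#'   `accel = c(t = ..., ax = ..., ay = ..., az = ...)` whose values name
#'   the columns in the files. Lets the reader ingest externally deposited
#'   tables with different headers.
#' @return A list of class `hr_streams` with tibbles `device_hr` (`t`,
#'   `bpm`), `ref_hr` (`t`, `bpm`) and `accel` (`t`, `ax`, `ay`, `az`).
#' @export
read_streams <- function(path, format = c("feather", "csv"),
                         columns = default_stream_columns()) {
  format <- match.arg(format)
  defaults <- default_stream_columns()
  for (s in names(defaults)) {
    columns[[s]] <- columns[[s]] %||% defaults[[s]]
  }
  parts <- lapply(names(STREAM_FILES), function(s) {
    read_one_stream(path, s, format, columns)
  })
  names(parts) <- names(STREAM_FILES)

  # Session-relative time axis: only re-base when absolute datetimes occur.
  if (any(vapply(parts, function(p) p$absolute, logical(1)))) {
    t0 <- min(vapply(parts, function(p) {
      if (nrow(p$data) > 0) min(p$data$t, na.rm = TRUE) else Inf
    }, numeric(1)))
    parts <- lapply(parts, function(p) {
      p$data$t <- p$data$t - t0
      p
    })
  }

  out <- lapply(names(parts), function(s) {
    d <- parts[[s]]$data
    finite <- rowSums(!is.finite(as.matrix(d))) == 0
    dropped <- sum(!finite)
    if (dropped > 0) {
      inform(sprintf("Dropped %d non-finite row(s) from %s stream.",
                     dropped, s))
    }
    dplyr::arrange(d[finite, , drop = FALSE], .data$t)
  })
  names(out) <- names(parts)
  structure(out, class = c("hr_streams", "list"))
}

#' Align device, reference and acceleration streams
#'
#' Produces the processed session table: one row per retained device
#' heart-rate reading, paired with the nearest-in-time reference reading
#' (ties resolve to the earlier reference sample) and with the acceleration
#' magnitudes recorded in the half-open window since the previous retained
#' device reading. Readings with no reference within `max_gap` seconds, or
#' with a heart rate outside `bpm_range`, are dropped; every drop between
#' two retained neighbours starts a new contiguity segment, which
#' downstream windowing never crosses.
#'
#' @param device_hr,ref_hr Tibbles with `t` (seconds) and `bpm`, sorted.
#' @param accel Tibble with `t`, `ax`, `ay`, `az`, sorted.
#' @param max_gap Maximum |device - reference| time difference (s).
#' @param bpm_range Plausibility bounds; readings outside are dropped from
#'   both heart-rate streams before matching.
#' @param participant_id Label stored in the output.
#' @return Tibble with columns `participant_id`, `segment_id`, `t_device`,
#'   `hr_device`, `t_ref`, `hr_ref` and list-column `accel_mags`.
#' @export
align_streams <- function(device_hr, ref_hr, accel, max_gap = 15,
                          bpm_range = c(20, 250),
                          participant_id = "session") {
  if (is.null(device_hr) || nrow(device_hr) == 0 ||
      is.null(ref_hr) || nrow(ref_hr) == 0) {
    abort("Device and reference streams must be non-empty.",
          class = "frugalhr_empty_input_error")
  }
  check_scalar_number(max_gap, "max_gap", min = 0, strict = TRUE)

  dev <- dplyr::arrange(as_tibble(device_hr), .data$t)
  dev <- dev[!duplicated(dev$t), , drop = FALSE]
  ref <- dplyr::arrange(as_tibble(ref_hr), .data$t)
  ref <- ref[ref$bpm >= bpm_range[1] & ref$bpm <= bpm_range[2], , drop = FALSE]
  if (nrow(ref) == 0) {
    abort("Reference stream is empty after cleaning.",
          class = "frugalhr_empty_input_error")
  }

  n <- nrow(dev)
  clean_ok <- dev$bpm >= bpm_range[1] & dev$bpm <= bpm_range[2]

  # Nearest reference per device reading; equidistant ties -> earlier.
  lo <- findInterval(dev$t, ref$t)
  lo_idx <- pmax(lo, 1L)
  hi_idx <- pmin(lo + 1L, nrow(ref))
  d_lo <- ifelse(lo >= 1L, abs(dev$t - ref$t[lo_idx]), Inf)
  d_hi <- ifelse(lo + 1L <= nrow(ref), abs(ref$t[hi_idx] - dev$t), Inf)
  nearest <- ifelse(d_lo <= d_hi, lo_idx, hi_idx)
  gap <- pmin(d_lo, d_hi)

  keep <- clean_ok & gap <= max_gap
  if (!any(keep)) {
    return(tibble(participant_id = character(), segment_id = integer(),
                  t_device = numeric(), hr_device = numeric(),
                  t_ref = numeric(), hr_ref = numeric(),
                  accel_mags = list()))
  }
  kept_idx <- which(keep)
  # New segment whenever at least one device reading was dropped between
  # retained neighbours.
  seg <- cumsum(c(1L, diff(kept_idx) > 1L))

  mags <- accel_magnitude(accel$ax, accel$ay, accel$az)
  t_acc <- accel$t
  prev_t <- c(-Inf, dev$t[kept_idx][-length(kept_idx)])
  accel_windows <- lapply(seq_along(kept_idx), function(j) {
    ti <- dev$t[kept_idx[j]]
    mags[t_acc > prev_t[j] & t_acc <= ti]
  })

  tibble(
    participant_id = participant_id,
    segment_id = as.integer(seg),
    t_device = dev$t[kept_idx],
    hr_device = dev$bpm[kept_idx],
    t_ref = ref$t[nearest[kept_idx]],
    hr_ref = ref$bpm[nearest[kept_idx]],
    accel_mags = accel_windows
  )
}

#' Write and read the processed session table
#'
#' The processed table round-trips through Feather (list-column preserved,
#' timestamps bit-exact) or CSV (acceleration magnitudes semicolon-joined
#' at full double precision, so values survive within 1e-9).
#'
#' @param dataset Aligned tibble from [align_streams()].
#' @param path Output file path.
#' @param format `"feather"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_processed <- function(dataset, path, format = c("feather", "csv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    abort(sprintf("Cannot write to %s", path), class = "frugalhr_io_error")
  }
  if (format == "feather") {
    arrow::write_feather(dataset, path)
  } else {
    flat <- dataset
    flat$accel_mags <- vapply(dataset$accel_mags, function(v) {
      paste(sprintf("%.17g", v), collapse = ";")
    }, character(1))
    readr::write_csv(flat, path)
  }
  invisible(path)
}

#' @rdname write_processed
#' @param columns Optional named character vector mapping the processed
#'   table's canonical column names (`participant_id`, `segment_id`,
#'   `t_device`, `hr_device`, `t_ref`, `hr_ref`, `accel_mags`) to the
#'   names used in the file, for ingesting externally deposited tables.
#' @export
read_processed <- function(path, format = c("feather", "csv"),
                           columns = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "frugalhr_io_error")
  }
  raw <- if (format == "feather") {
    as_tibble(arrow::read_feather(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(accel_mags = readr::col_character()))
  }
  canonical <- c("participant_id", "segment_id", "t_device", "hr_device",
                 "t_ref", "hr_ref", "accel_mags")
  if (!is.null(columns)) {
    map <- columns
    missing_cols <- setdiff(unname(map), names(raw))
    if (length(missing_cols) > 0) {
      abort(sprintf("Processed table is missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            class = "frugalhr_schema_error")
    }
    raw <- raw[unname(map)]
    names(raw) <- names(map)
  }
  missing_cols <- setdiff(canonical, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Processed table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "frugalhr_schema_error")
  }
  out <- raw[canonical]
  if (is.character(out$accel_mags)) {
    out$accel_mags <- lapply(out$accel_mags, function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";")[[1]])
    })
  } else {
    out$accel_mags <- lapply(out$accel_mags, as.numeric)
  }
  out$segment_id <- as.integer(out$segment_id)
  out
}
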