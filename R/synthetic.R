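# Synthetic paired-device session generator.
#
# Emulates the laboratory setting the correction method targets: a wrist
# wearable reporting heart rate roughly every 12 s plus ~4 Hz acceleration,
# and a chest-worn ECG reference reporting every 15 s. The reference is
# treated as gold: its samples equal the simulated true heart rate exactly.
# Device readings are corrupted with motion-dependent Gaussian error and
# occasional large spikes, the two phenomena the correction model exploits.

#' Activity protocol for a simulated session
#'
#' Builds the phase table that drives the true heart-rate trajectory and the
#' acceleration statistics of a synthetic session. The default mirrors the
#' laboratory procedure the method was developed for: alternating 5-min
#' breaks with treadmill walks at 5 and 3 km/h and upper-lift exercises,
#' 85 minutes in total.
#'
#' `hr_target` is the steady-state heart rate the trajectory relaxes towards
#' during the phase (BPM); `intensity` scales the oscillatory component of
#' the wrist acceleration (in g) and is what makes device noise
#' motion-dependent.
#'
#' @param phases Optional tibble with columns `activity`, `duration_min`,
#'   `hr_target`, `intensity` to replace the default protocol.
#' @return A tibble with one row per phase, in session order.
#' @export
#' @examples
#' hr_protocol()
hr_protocol <- function(phases = NULL) {
  if (!is.null(phases)) {
    req <- c("activity", "duration_min", "hr_target", "intensity")
    missing_cols <- setdiff(req, names(phases))
    if (length(missing_cols) > 0) {
      abort(paste0("Protocol is missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "frugalhr_schema_error")
    }
    if (any(phases$duration_min <= 0)) {
      abort("All phase durations must be positive.",
            class = "frugalhr_domain_error")
    }
    out <- as_tibble(phases)[req]
  } else {
    out <- tibble(
      activity = c("break", "walk_5kmh", "break", "walk_3kmh", "break",
                   "walk_5kmh", "break", "lift_dynamic", "break",
                   "lift_calm", "break"),
      duration_min = c(5, 15, 5, 15, 5, 15, 5, 5, 5, 5, 5),
      hr_target = c(70, 115, 70, 95, 70, 115, 70, 120, 70, 100, 70),
      intensity = c(0.05, 0.8, 0.05, 0.5, 0.05, 0.8, 0.05, 1.2, 0.05,
                    0.3, 0.05)
    )
  }
  dplyr::mutate(out,
                phase = dplyr::row_number(),
                t_start = cumsum(c(0, .data$duration_min[-dplyr::n()])) * 60,
                t_end = cumsum(.data$duration_min) * 60,
                .before = 1)
}

#' Measurement noise model for the synthetic device
#'
#' Parameters of the corruption applied to the wrist device's heart-rate
#' stream and the cadences of the three streams. The device error standard
#' deviation for a reading is `baseline_sd + coupling * IQR` where IQR is
#' the interquartile range of the acceleration magnitudes in the reading's
#' preceding inter-reading window; spikes are additive, sign-symmetric and
#' drawn uniformly from `spike_amp`.
#'
#' @param baseline_sd Motion-free error sd (BPM).
#' @param coupling Extra error sd per unit of window acceleration IQR
#'   (BPM per g).
#' @param spike_prob Per-reading probability of a sudden spike.
#' @param spike_amp Length-2 range of spike magnitudes (BPM).
#' @param device_interval Mean wrist-device reading interval (s).
#' @param device_jitter If `TRUE` (default) inter-reading intervals are
#'   exponential with the stated mean; if `FALSE` the device samples on an
#'   exact grid.
#' @param ref_interval Reference (ECG) sampling interval (s), exact.
#' @param accel_rate Acceleration sampling rate (Hz).
#' @param tau Heart-rate relaxation time constant (s).
#' @return A list of class `hr_noise_model`.
#' @export
noise_model <- function(baseline_sd = 10, coupling = 40, spike_prob = 0.15,
                        spike_amp = c(30, 80), device_interval = 12,
                        device_jitter = TRUE, ref_interval = 15,
                        accel_rate = 4, tau = 45) {
  check_scalar_number(baseline_sd, "baseline_sd", min = 0)
  check_scalar_number(coupling, "coupling", min = 0)
  check_scalar_number(spike_prob, "spike_prob", min = 0)
  if (spike_prob > 1) {
    abort("`spike_prob` must lie in [0, 1].", class = "frugalhr_domain_error")
  }
  if (length(spike_amp) != 2L || any(!is.finite(spike_amp)) ||
      any(spike_amp < 0) || spike_amp[2] < spike_amp[1]) {
    abort("`spike_amp` must be a non-decreasing, non-negative length-2 range.",
          class = "frugalhr_domain_error")
  }
  check_scalar_number(device_interval, "device_interval", min = 0, strict = TRUE)
  check_scalar_number(ref_interval, "ref_interval", min = 0, strict = TRUE)
  check_scalar_number(accel_rate, "accel_rate", min = 0, strict = TRUE)
  check_scalar_number(tau, "tau", min = 0, strict = TRUE)
  structure(
    list(baseline_sd = baseline_sd, coupling = coupling,
         spike_prob = spike_prob, spike_amp = as.numeric(spike_amp),
         device_interval = device_interval,
         device_jitter = isTRUE(device_jitter),
         ref_interval = ref_interval, accel_rate = accel_rate, tau = tau),
    class = "hr_noise_model"
  )
}

#' Simulate the true heart-rate trajectory of a protocol
#'
#' Integrates first-order relaxation dynamics
#' `dHR/dt = (target(phase) - HR) / tau` on a fixed grid, using the exact
#' exponential update per step so the trajectory is stable for any step
#' size. The trajectory is continuous across phase boundaries: each phase
#' starts from the heart rate the previous phase ended at.
#'
#' @param protocol Phase table from [hr_protocol()].
#' @param tau Relaxation time constant (s).
#' @param hr_rest Initial heart rate (BPM).
#' @param step Integration/sampling step (s).
#' @return Tibble with columns `t`, `hr_true`, `phase`, `activity`,
#'   `intensity`, sampled every `step` seconds from 0 to session end.
#' @export
simulate_true_hr <- function(protocol = hr_protocol(), tau = 45,
                             hr_rest = 70, step = 0.25) {
  check_scalar_number(tau, "tau", min = 0, strict = TRUE)
  check_scalar_number(step, "step", min = 0, strict = TRUE)
  duration <- max(protocol$t_end)
  t <- seq(0, duration, by = step)
  phase_idx <- findInterval(t, protocol$t_start, rightmost.closed = FALSE)
  phase_idx[phase_idx < 1L] <- 1L
  target <- protocol$hr_target[phase_idx]
  decay <- exp(-step / tau)
  hr <- numeric(length(t))
  hr[1] <- hr_rest
  for (i in seq_along(t)[-1]) {
    hr[i] <- target[i] + (hr[i - 1] - target[i]) * decay
  }
  tibble(
    t = t,
    hr_true = hr,
    phase = protocol$phase[phase_idx],
    activity = protocol$activity[phase_idx],
    intensity = protocol$intensity[phase_idx]
  )
}

#' Sample device, reference and acceleration streams from a trajectory
#'
#' Produces the three raw streams a real session yields. The reference
#' samples the true trajectory exactly every `ref_interval` seconds. The
#' acceleration stream runs at `accel_rate` Hz; its magnitude combines a
#' gravity component with an arm-swing oscillation and white noise, both
#' scaled by the phase intensity. Device readings arrive at
#' exponential-jittered (or exact) intervals around `device_interval` and
#' carry Gaussian error whose sd grows with the acceleration IQR of the
#' preceding inter-reading window, plus occasional sign-symmetric spikes.
#'
#' @param trajectory Output of [simulate_true_hr()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; output is reproducible per (seed, parameters).
#' @param participant_id Label stored with the session.
#' @return A list of class `hr_session` with elements `truth`, `device_hr`
#'   (`t`, `bpm`), `ref_hr` (`t`, `bpm`), `accel` (`t`, `ax`, `ay`, `az`),
#'   `noise`, `participant_id`.
#' @export
sample_streams <- function(trajectory, noise = noise_model(), seed = 1,
                           participant_id = "synthetic") {
  stopifnot(inherits(noise, "hr_noise_model"))
  set.seed(as.integer(seed))
  duration <- max(trajectory$t)
  hr_at <- function(t) approx(trajectory$t, trajectory$hr_true, xout = t,
                              rule = 2)$y
  intensity_at <- function(t) {
    idx <- pmax(1L, findInterval(t, trajectory$t))
    trajectory$intensity[idx]
  }

  # Acceleration: gravity on z plus an arm-swing oscillation (~1.8 Hz) on
  # x/y whose amplitude follows the phase intensity, with white noise.
  ta <- seq(1 / noise$accel_rate, duration, by = 1 / noise$accel_rate)
  inten <- intensity_at(ta)
  swing <- 2 * pi * 1.8 * ta
  noise_sd <- 0.03 + 0.08 * inten
  accel <- tibble(
    t = ta,
    ax = inten * sin(swing) + rnorm(length(ta), 0, noise_sd),
    ay = 0.5 * inten * sin(swing + 1.3) + rnorm(length(ta), 0, noise_sd),
    az = 1 + 0.2 * inten * cos(swing) + rnorm(length(ta), 0, noise_sd)
  )
  accel_mag <- sqrt(accel$ax^2 + accel$ay^2 + accel$az^2)

  # Reference: exact truth on an exact grid.
  tr <- seq(noise$ref_interval, duration, by = noise$ref_interval)
  ref_hr <- tibble(t = tr, bpm = hr_at(tr))

  # Device: jittered sampling; error sd coupled to the window accel IQR.
  if (noise$device_jitter) {
    td <- numeric(0)
    t_cur <- 0
    repeat {
      t_cur <- t_cur + rexp(1, rate = 1 / noise$device_interval)
      if (t_cur > duration) break
      td <- c(td, t_cur)
    }
  } else {
    td <- seq(noise$device_interval, duration, by = noise$device_interval)
  }
  n_dev <- length(td)
  prev <- c(0, td[-n_dev])
  win_iqr <- vapply(seq_len(n_dev), function(i) {
    m <- accel_mag[accel$t > prev[i] & accel$t <= td[i]]
    if (length(m) == 0) 0 else unname(stats::quantile(m, 0.75) -
                                        stats::quantile(m, 0.25))
  }, numeric(1))
  err_sd <- noise$baseline_sd + noise$coupling * win_iqr
  err <- rnorm(n_dev, 0, err_sd)
  spikes <- rbinom(n_dev, 1, noise$spike_prob) *
    sample(c(-1, 1), n_dev, replace = TRUE) *
    runif(n_dev, noise$spike_amp[1], noise$spike_amp[2])
  device_hr <- tibble(t = td, bpm = hr_at(td) + err + spikes)

  structure(
    list(truth = trajectory, device_hr = device_hr, ref_hr = ref_hr,
         accel = accel, noise = noise, participant_id = participant_id,
         seed = as.integer(seed)),
    class = "hr_session"
  )
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: [simulate_true_hr()] followed by [sample_streams()].
#'
#' @inheritParams sample_streams
#' @inheritParams simulate_true_hr
#' @return An `hr_session`; see [sample_streams()].
#' @export
simulate_session <- function(protocol = hr_protocol(), noise = noise_model(),
                             seed = 1, participant_id = "synthetic",
                             hr_rest = 70, step = 0.25) {
  traj <- simulate_true_hr(protocol, tau = noise$tau, hr_rest = hr_rest,
                           step = step)
  sample_streams(traj, noise = noise, seed = seed,
                 participant_id = participant_id)
}

#' Write a synthetic session as raw stream files
#'
#' Writes `device_hr`, `ref_hr` and `accel` files in the layout
#' [read_streams()] expects, so the full pipeline can run end-to-end on
#' simulated data.
#'
#' @param session An `hr_session`.
#' @param path Directory to create/write into.
#' @param format `"feather"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
session_to_raw_files <- function(session, path, format = c("feather", "csv")) {
  stopifnot(inherits(session, "hr_session"))
  format <- match.arg(format)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  writer <- if (format == "feather") arrow::write_feather else readr::write_csv
  ext <- if (format == "feather") "feather" else "csv"
  writer(session$device_hr, file.path(path, paste0("device_hr.", ext)))
  writer(session$ref_hr, file.path(path, paste0("ref_hr.", ext)))
  writer(session$accel, file.path(path, paste0("accel.", ext)))
  invisible(path)
}

#' @export
print.hr_session <- function(x, ...) {
  cat(sprintf(
    "<hr_session> participant %s: %.1f min, %d device / %d reference HR readings, %d accel samples\n",
    x$participant_id, max(x$truth$t) / 60, nrow(x$device_hr),
    nrow(x$ref_hr), nrow(x$accel)))
  invisible(x)
}
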