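#' Construct a tri-axial trunk acceleration recording
#'
#' A recording is a data frame with columns `t` (s), `ap`, `ml`, `vt`
#' (anteroposterior, mediolateral, vertical acceleration in g, vertical
#' positive up per the ISB convention) and attributes `sampling_rate`,
#' `subject_id`, `task`. Sampling must be uniform: the maximum timestamp
#' jitter is required to be under half a sample period.
#'
#' @param t,ap,ml,vt equal-length numeric vectors.
#' @param sampling_rate sampling frequency in Hz.
#' @param subject_id,task optional labels.
#' @return A data frame of class `accel_recording`.
#' @export
acceleration_recording <- function(t, ap, ml, vt, sampling_rate,
                                   subject_id = NA_character_,
                                   task = NA_character_) {
  n <- length(t)
  if (!all(lengths(list(ap, ml, vt)) == n))
    stop_gaitssc("axis vectors must match the timestamp length")
  check_number(sampling_rate, "sampling_rate", lower = 1e-6)
  if (n >= 2) {
    jitter <- max(abs(diff(t) - 1 / sampling_rate))
    if (jitter > 0.5 / sampling_rate)
      stop_gaitssc("non-uniform sampling: max jitter %.3g s exceeds half a sample period", jitter)
  }
  rec <- data.frame(t = t, ap = ap, ml = ml, vt = vt)
  attr(rec, "sampling_rate") <- sampling_rate
  attr(rec, "subject_id") <- subject_id
  attr(rec, "task") <- task
  class(rec) <- c("accel_recording", "data.frame")
  rec
}

sampling_rate <- function(rec) attr(rec, "sampling_rate")

rec_with <- function(rec, ap = rec$ap, ml = rec$ml, vt = rec$vt, t = rec$t) {
  acceleration_recording(t, ap, ml, vt, attr(rec, "sampling_rate"),
                         attr(rec, "subject_id"), attr(rec, "task"))
}

#' Per-task gait profile for the signal generator
#'
#' @param mean_step_time mean step time (s).
#' @param step_time_cov step-time coefficient of variation (%).
#' @param accel_rms target RMS of the 3 Hz low-passed, gravity-free
#'   vertical acceleration (g).
#' @param step_length mean step length (m).
#' @param asymmetry_ratio ratio of the two feet's mean step times (>= 1).
#' @param double_support_frac double-support phase (initial contact to
#'   opposite-foot final contact) as a fraction of the stride, in (0, 0.5).
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(mean_step_time, step_time_cov, accel_rms,
                         step_length, asymmetry_ratio = 1.02,
                         double_support_frac = 0.12) {
  check_number(mean_step_time, "mean_step_time", lower = 1e-6)
  check_number(step_time_cov, "step_time_cov", lower = 0)
  check_number(accel_rms, "accel_rms", lower = 1e-9)
  check_number(step_length, "step_length", lower = 1e-6)
  check_number(asymmetry_ratio, "asymmetry_ratio", lower = 1)
  if (double_support_frac <= 0 || double_support_frac >= 0.5)
    stop_gaitssc("double_support_frac must lie in (0, 0.5)")
  structure(list(mean_step_time = mean_step_time, step_time_cov = step_time_cov,
                 accel_rms = accel_rms, step_length = step_length,
                 asymmetry_ratio = asymmetry_ratio,
                 double_support_frac = double_support_frac),
            class = "gait_profile")
}

#' Draw a subject-level variant of a gait profile
#'
#' Real cohorts spread around their group means; this applies lognormal
#' multiplicative jitter to each profile parameter (defaults: sd 0.10 on
#' step time, 0.40 on its CoV, 0.22 on RMS, 0.12 on step length, 0.12 on
#' the double-support fraction, placing the strongest group contrasts
#' near a standardized separation of one), clamped to physiological ranges. The
#' random factors are drawn from the current RNG state, so a per-subject
#' seed gives each subject one consistent deviation from the group mean.
#'
#' @param profile a [gait_profile()].
#' @param sds named multiplicative log-sds for the parameters.
#' @param scale common multiplier on all sds (e.g. to model erratic task
#'   compliance in a subgroup).
#' @param factors optional pre-drawn multipliers (named like `sds`),
#'   e.g. one subject-level draw shared across tasks.
#' @return A jittered [gait_profile()].
#' @export
jitter_gait_profile <- function(profile,
                                sds = c(mean_step_time = 0.10,
                                        step_time_cov = 0.40,
                                        accel_rms = 0.22,
                                        step_length = 0.12,
                                        double_support_frac = 0.12),
                                scale = 1, factors = NULL) {
  f <- factors %||% exp(rnorm(length(sds), 0, scale * sds))
  names(f) <- names(sds)
  gait_profile(
    mean_step_time = min(max(profile$mean_step_time * f[["mean_step_time"]], 0.3), 1.2),
    step_time_cov = min(max(profile$step_time_cov * f[["step_time_cov"]], 0.5), 15),
    accel_rms = profile$accel_rms * f[["accel_rms"]],
    step_length = profile$step_length * f[["step_length"]],
    asymmetry_ratio = profile$asymmetry_ratio,
    double_support_frac = min(max(profile$double_support_frac *
                                    f[["double_support_frac"]], 0.05), 0.45))
}

#' Default group gait profiles
#'
#' Encodes the qualitative group ordering reported for this kind of cohort:
#' step/stride-time variability largest in the impaired elderly, smaller in
#' healthy elderly, smallest in young adults; cadence, vertical-acceleration
#' RMS, step length and speed largest in young adults. Fast walking shortens
#' step time and raises RMS; dual tasks do the opposite, more so for the
#' hard task. Magnitudes are free modeling choices giving clear but
#' non-degenerate group separation.
#'
#' @return Nested list: `profiles[[group]][[task]]` is a [gait_profile()].
#' @export
default_gait_profiles <- function() {
  mk <- function(st, cov, rms, lg, asym, dsf)
    gait_profile(st, cov, rms, lg, asym, dsf)
  list(
    "YA" = list(
      NormalW = mk(0.52, 1.8, 0.22, 0.70, 1.02, 0.11),
      EasyD   = mk(0.54, 2.1, 0.21, 0.68, 1.02, 0.11),
      HardD   = mk(0.56, 2.5, 0.20, 0.66, 1.03, 0.12),
      FastW   = mk(0.42, 1.5, 0.30, 0.82, 1.02, 0.10)),
    "HE" = list(
      NormalW = mk(0.56, 2.9, 0.18, 0.62, 1.04, 0.13),
      EasyD   = mk(0.58, 3.3, 0.17, 0.60, 1.04, 0.13),
      HardD   = mk(0.61, 3.9, 0.16, 0.57, 1.05, 0.14),
      FastW   = mk(0.46, 2.5, 0.24, 0.72, 1.04, 0.12)),
    "MCI-E" = list(
      NormalW = mk(0.60, 4.6, 0.14, 0.54, 1.07, 0.15),
      EasyD   = mk(0.63, 5.3, 0.13, 0.52, 1.07, 0.16),
      HardD   = mk(0.66, 6.1, 0.12, 0.50, 1.08, 0.16),
      FastW   = mk(0.50, 4.2, 0.19, 0.62, 1.06, 0.14)))
}

# Draw one direction's worth of step intervals and ground-truth events.
# Returns IC/FC times relative to the direction start and per-step times.
synth_direction_events <- function(profile, distance) {
  n_steps <- max(4L, ceiling(distance / profile$step_length) + 1L)
  a <- profile$asymmetry_ratio
  foot_mean <- profile$mean_step_time * c(2 * a / (1 + a), 2 / (1 + a))
  sd_step <- profile$step_time_cov / 100 * profile$mean_step_time
  foot <- rep_len(c("F1", "F2"), n_steps)
  tau <- rnorm(n_steps, foot_mean[rep_len(1:2, n_steps)], sd_step)
  tau <- pmax(tau, 0.25 * profile$mean_step_time)
  ic <- c(0, cumsum(tau))[seq_len(n_steps)]
  stride <- tau + c(tau[-1], tau[n_steps]) # IC_k to same-foot next IC
  fc <- ic + profile$double_support_frac * stride
  fc_foot <- c(foot[-1], setdiff(c("F1", "F2"), foot[n_steps])[1])
  list(ic = ic, fc = fc, foot = foot, fc_foot = fc_foot, tau = tau,
       duration = ic[n_steps] + tau[n_steps])
}

# Two-harmonic per-step vertical waveform on a time grid (g units, unscaled).
step_waveform <- function(tt, ic, tau, t0 = 0) {
  w <- numeric(length(tt))
  starts <- ic + t0
  idx <- findInterval(tt, starts)
  inside <- idx >= 1 & idx <= length(ic) & tt < starts[length(ic)] + tau[length(ic)]
  u <- (tt[inside] - starts[idx[inside]]) / tau[idx[inside]]
  # global minimum at u = 0 (the initial contact), one clear trough per step
  w[inside] <- -(cos(2 * pi * u) + 0.45 * cos(4 * pi * u))
  w
}

#' Generate a synthetic trunk acceleration recording with ground truth
#'
#' Simulates a 2 x `distance` walk: two straight segments separated by a
#' low-amplitude turn gap. The vertical axis carries a periodic two-harmonic
#' per-step waveform whose step intervals are drawn i.i.d. around the
#' profile's mean step time with its CoV, scaled so the RMS of the 3 Hz
#' low-passed signal equals the profile's `accel_rms`. Gravity (1 g) and a
#' small static tilt are applied to all axes. Ground-truth initial contacts
#' (IC, step onsets) and final contacts (FC, opposite-foot toe-offs at
#' IC + double-support fraction of the stride) are returned alongside.
#'
#' @param profile a [gait_profile()].
#' @param task task label.
#' @param distance one-direction walking distance (m).
#' @param sampling_rate sampling frequency (Hz), >= 50.
#' @param seed integer seed.
#' @param turn_duration low-activity gap between directions (s).
#' @param tilt_deg static sensor tilt about the mediolateral axis (degrees).
#' @param noise_sd white measurement noise on each axis (g).
#' @param subject_id subject label carried on the recording.
#' @return A list with `recording` (an [acceleration_recording()]),
#'   `events` (data frame `event,time,foot`), and `turn` (start/end of the
#'   true turn gap, s).
#' @export
generate_acceleration <- function(profile, task = "NormalW", distance = 20,
                                  sampling_rate = 100, seed = 1L,
                                  turn_duration = 3, tilt_deg = 3,
                                  noise_sd = 0.01, subject_id = NA_character_) {
  stopifnot(inherits(profile, "gait_profile"))
  if (sampling_rate < 50) stop_gaitssc("sampling_rate must be >= 50 Hz")
  check_number(distance, "distance", lower = 1e-6)
  set.seed(seed)

  d1 <- synth_direction_events(profile, distance)
  d2 <- synth_direction_events(profile, distance)
  min_dur <- 2 * 2 * profile$mean_step_time + 6
  if (d1$duration < min_dur || d2$duration < min_dur)
    stop_gaitssc(paste0("segment too short (%.1f s): need at least 2 strides",
                        " plus the 6 s trim margin (%.1f s); increase the",
                        " distance or shorten the step length"),
                 min(d1$duration, d2$duration), min_dur)

  t2_start <- d1$duration + turn_duration
  total <- t2_start + d2$duration
  tt <- seq(0, total, by = 1 / sampling_rate)

  w <- step_waveform(tt, d1$ic, d1$tau, 0) + step_waveform(tt, d2$ic, d2$tau, t2_start)
  # scale so the 3 Hz low-passed walking-portion RMS matches the profile
  wf <- lowpass_filter(w, sampling_rate)
  walking <- wf[tt < d1$duration | tt >= t2_start]
  scale <- profile$accel_rms / sqrt(mean(walking^2))
  vt_dyn <- scale * w

  # mild locomotor content on the horizontal axes plus white noise
  ap_dyn <- 0.3 * vt_dyn
  ml_dyn <- 0.2 * scale * sin(pi * tt / profile$mean_step_time)
  ml_dyn[tt >= d1$duration & tt < t2_start] <- 0

  g_vec <- c(0, 0, 1)
  axes <- rbind(ap = ap_dyn, ml = ml_dyn, vt = vt_dyn) + g_vec # gravity on vt
  th <- tilt_deg * pi / 180 # static tilt: rotate about the ml axis
  rot <- matrix(c(cos(th), 0, -sin(th),
                  0, 1, 0,
                  sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  axes <- rot %*% axes + matrix(rnorm(3 * length(tt), 0, noise_sd), 3)

  rec <- acceleration_recording(tt, axes[1, ], axes[2, ], axes[3, ],
                                sampling_rate, subject_id, task)
  ev <- rbind(
    data.frame(event = "IC", time = c(d1$ic, t2_start + d2$ic),
               foot = c(d1$foot, d2$foot), stringsAsFactors = FALSE),
    data.frame(event = "FC", time = c(d1$fc, t2_start + d2$fc),
               foot = c(d1$fc_foot, d2$fc_foot), stringsAsFactors = FALSE))
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL
  list(recording = rec, events = ev,
       turn = c(start = d1$duration, end = t2_start))
}

#' Column names of the 96-measure gait feature table
#'
#' `<task>::<stgf>` for the four walking tasks (64 columns) followed by
#' `dtc::<dualtask>::<stgf>` for the two dual tasks (32 columns).
#'
#' @return Character vector of length 96.
#' @export
feature_column_names <- function() {
  c(as.vector(t(outer(.task_names, .stgf_names, paste, sep = "::"))),
    as.vector(t(outer(paste0("dtc::", .dual_tasks), .stgf_names, paste, sep = "::"))))
}

#' Generate a feature table directly, with planted group effects
#'
#' Bypasses the signal stage: 96 standard-normal columns (named as the real
#' feature table) with the planted columns shifted by `effect_size` standard
#' deviations in the MCI-E group. Used to exercise the classifier stages
#' under a known ground truth.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param planted_features integer indices in 1..96 receiving the shift.
#' @param effect_size standardized shift (Cohen's d) applied to MCI-E rows.
#' @param seed integer seed.
#' @param block_rho optional common correlation within each task's 16-column
#'   block (0 = independent columns).
#' @return A data frame: `id`, `group`, then 96 numeric feature columns.
#' @export
generate_feature_table <- function(cohort, planted_features = integer(0),
                                   effect_size = 0, seed = 1L, block_rho = 0) {
  cols <- feature_column_names()
  p <- length(cols)
  planted_features <- as.integer(planted_features)
  if (length(planted_features) &&
      (min(planted_features) < 1L || max(planted_features) > p))
    stop_gaitssc("planted feature indices must lie in 1..%d", p)
  check_number(effect_size, "effect_size", lower = 0)
  set.seed(seed)
  n <- nrow(cohort)
  X <- matrix(rnorm(n * p), n, p)
  if (block_rho > 0) {
    for (b in seq_len(p %/% 16)) {
      j <- ((b - 1) * 16 + 1):(b * 16)
      shared <- rnorm(n)
      X[, j] <- sqrt(block_rho) * shared + sqrt(1 - block_rho) * X[, j]
    }
  }
  X[cohort$group == "MCI-E", planted_features] <-
    X[cohort$group == "MCI-E", planted_features, drop = FALSE] + effect_size
  colnames(X) <- cols
  out <- data.frame(id = cohort$id, group = cohort$group, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(X, check.names = FALSE))
}
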