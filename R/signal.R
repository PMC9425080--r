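#' Map device axes onto the ISB anatomical convention
#'
#' Reorders and sign-flips the three device axes so the output columns are
#' anteroposterior, mediolateral and vertical (positive up). The mapping is
#' a signed permutation such as `c(ap = "-y", ml = "+x", vt = "+z")`, read
#' as "anatomical axis <- signed device axis"; device axes are the 2nd-4th
#' columns of the input, in x, y, z order.
#'
#' @param raw a data frame whose columns are time then the three device
#'   axes (an [acceleration_recording()] is accepted: its `ap`, `ml`, `vt`
#'   columns are then treated as device x, y, z).
#' @param mapping named character vector over `ap`, `ml`, `vt` with values
#'   in `+x,-x,+y,-y,+z,-z`, jointly a signed permutation.
#' @param sampling_rate required when `raw` carries no `sampling_rate`
#'   attribute.
#' @return An [acceleration_recording()].
#' @export
transform_axes <- function(raw, mapping = c(ap = "+x", ml = "+y", vt = "+z"),
                           sampling_rate = NULL) {
  need <- c("ap", "ml", "vt")
  if (!all(need %in% names(mapping))) stop_gaitssc("mapping must name ap, ml, vt")
  mapping <- mapping[need]
  ax <- sub("^[+-]", "", mapping)
  sg <- ifelse(substr(mapping, 1, 1) == "-", -1, 1)
  if (!setequal(ax, c("x", "y", "z")) || anyDuplicated(ax) ||
      !all(mapping %in% c("+x", "-x", "+y", "-y", "+z", "-z")))
    stop_gaitssc("mapping must be a signed permutation of x, y, z")
  fs <- sampling_rate %||% attr(raw, "sampling_rate")
  if (is.null(fs)) stop_gaitssc("sampling_rate is required")
  dev <- as.matrix(raw[, -1, drop = FALSE])[, 1:3, drop = FALSE]
  colnames(dev) <- c("x", "y", "z")
  acceleration_recording(raw[[1]],
                         sg[1] * dev[, ax[1]], sg[2] * dev[, ax[2]],
                         sg[3] * dev[, ax[3]], fs,
                         attr(raw, "subject_id") %||% NA_character_,
                         attr(raw, "task") %||% NA_character_)
}

# Rodrigues rotation taking unit vector a onto unit vector b.
rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (1 - cth < 1e-12) return(diag(3))
  if (1 + cth < 1e-12) # antipodal: half-turn about any orthogonal axis
    return(diag(c(1, -1, -1)))
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Dynamic tilt correction of a trunk recording
#'
#' Moe-Nilssen-style correction for imprecise sensor placement: the mean
#' acceleration vector (dominated by gravity during steady walking) is
#' rotated onto the vertical axis, so the mean horizontal accelerations
#' become zero; 1 g is then subtracted from the vertical axis, leaving a
#' gravity-free recording. Inputs whose mean acceleration magnitude is
#' below 0.5 g are treated as already gravity-compensated (1 g is re-added
#' internally before estimating the rotation), which makes the correction
#' idempotent.
#'
#' @param rec an [acceleration_recording()] with at least 2 s of data.
#' @return A gravity-free, tilt-corrected [acceleration_recording()].
#' @export
tilt_correct <- function(rec) {
  fs <- sampling_rate(rec)
  if (nrow(rec) < 2 * fs) stop_gaitssc("tilt correction needs at least 2 s of data")
  A <- cbind(rec$ap, rec$ml, rec$vt)
  m <- colMeans(A)
  if (isTRUE(attr(rec, "gravity_free")) || sqrt(sum(m^2)) < 0.5) {
    # gravity-compensated input: restore gravity internally
    A[, 3] <- A[, 3] + 1
    m <- m + c(0, 0, 1)
  }
  nm <- sqrt(sum(m^2))
  if (nm < 0.05)
    stop_gaitssc("mean acceleration magnitude %.3g g is too small (free fall?)", nm)
  R <- rotation_onto(m / nm, c(0, 0, 1))
  A <- A %*% t(R)
  out <- rec_with(rec, ap = A[, 1], ml = A[, 2], vt = A[, 3] - 1)
  attr(out, "gravity_free") <- TRUE
  out
}

#' Zero-lag low-pass Butterworth filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the net response is zero-phase with an 8th-order magnitude roll-off.
#' Defaults follow the gait-processing convention of a 3 Hz cutoff.
#'
#' @param x numeric signal.
#' @param sampling_rate sampling frequency (Hz).
#' @param cutoff low-pass cutoff (Hz), below Nyquist.
#' @param order filter order of each pass.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, sampling_rate, cutoff = 3, order = 4) {
  if (cutoff >= sampling_rate / 2)
    stop_gaitssc("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, sampling_rate / 2)
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  n <- length(x)
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  np <- min(n - 1L, ceiling(3 * sampling_rate / cutoff))
  xp <- c(2 * x[1] - x[(np + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1L):(np + n)]
}

# Apply the low-pass to all three axes of a recording.
lowpass_recording <- function(rec, cutoff = 3, order = 4) {
  fs <- sampling_rate(rec)
  rec_with(rec,
           ap = lowpass_filter(rec$ap, fs, cutoff, order),
           ml = lowpass_filter(rec$ml, fs, cutoff, order),
           vt = lowpass_filter(rec$vt, fs, cutoff, order))
}

#' Split a two-direction walk at the turn and trim segment edges
#'
#' Locates the turn as the longest sustained (>= `min_gap` s) window whose
#' vertical-dynamics RMS falls below `rel_threshold` times the whole-recording
#' RMS, splits at its midpoint, and removes the first and last `trim`
#' seconds of each resulting segment.
#'
#' @param rec a tilt-corrected (gravity-free) [acceleration_recording()].
#' @param trim seconds removed from each end of each segment.
#' @param min_gap minimum duration of the low-activity turn window (s).
#' @param rel_threshold turn-detection RMS threshold relative to the
#'   whole-recording RMS.
#' @return A list of two [acceleration_recording()]s (outbound, return),
#'   original timestamps preserved; `attr(,"split_time")` records the cut.
#' @export
split_segments <- function(rec, trim = 3, min_gap = 1, rel_threshold = 0.2) {
  fs <- sampling_rate(rec)
  v <- rec$vt - mean(rec$vt)
  w <- max(3L, round(min_gap * fs))
  ma <- stats::filter(v^2, rep(1 / w, w), sides = 2)
  roll <- sqrt(as.numeric(ma))
  low <- !is.na(roll) & roll < rel_threshold * sqrt(mean(v^2))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  runs <- which(r$values & r$lengths >= w)
  if (!length(runs))
    stop_gaitssc("no turn detected: no sustained low-activity window below %g x RMS",
                 rel_threshold)
  k <- runs[which.max(r$lengths[runs])]
  mid <- ends[k] - r$lengths[k] / 2
  split_time <- rec$t[1] + (mid - 1) / fs

  seg <- function(i1, i2) {
    if ((i2 - i1 + 1) / fs < 2 * trim)
      stop_gaitssc("segment of %.1f s is shorter than twice the %g s trim",
                   (i2 - i1 + 1) / fs, trim)
    keep <- (i1 + round(trim * fs)):(i2 - round(trim * fs))
    rec_with(rec, t = rec$t[keep], ap = rec$ap[keep],
             ml = rec$ml[keep], vt = rec$vt[keep])
  }
  out <- list(seg(1L, floor(mid)), seg(floor(mid) + 1L, nrow(rec)))
  attr(out, "split_time") <- split_time
  out
}
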