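#' Construct and validate a set of gait events
#'
#' Gait events are the initial contacts (IC, heel strikes) and final
#' contacts (FC, toe-offs) of the gait cycle. Invariants enforced: both
#' series strictly increasing, the first event is an IC, exactly one FC
#' lies strictly between consecutive ICs (so there are `n_ic - 1` FCs),
#' and IC foot labels strictly alternate. The FC between two ICs is
#' labeled with the foot of the following IC (the foot lifting off after
#' its contralateral partner lands).
#'
#' @param ic_times,fc_times event times (s).
#' @param first_foot label of the first IC's foot (`"F1"` or `"F2"`);
#'   left/right identity is arbitrary.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(ic_times, fc_times, first_foot = "F1") {
  ic_times <- as.numeric(ic_times); fc_times <- as.numeric(fc_times)
  n <- length(ic_times)
  if (n < 2L) stop_gaitssc("need at least 2 initial contacts")
  if (any(diff(ic_times) <= 0) || (length(fc_times) > 1 && any(diff(fc_times) <= 0)))
    stop_gaitssc("event times must be strictly increasing")
  if (length(fc_times) != n - 1L)
    stop_gaitssc("expected exactly one FC between consecutive ICs (%d ICs, %d FCs)",
                 n, length(fc_times))
  if (length(fc_times) &&
      (any(fc_times <= ic_times[-n]) || any(fc_times >= ic_times[-1])))
    stop_gaitssc("each FC must lie strictly between its flanking ICs")
  feet <- c("F1", "F2")
  if (!first_foot %in% feet) stop_gaitssc("first_foot must be 'F1' or 'F2'")
  ic_foot <- rep_len(if (first_foot == "F1") feet else rev(feet), n)
  structure(list(ic_times = ic_times, fc_times = fc_times,
                 ic_foot = ic_foot, fc_foot = ic_foot[-1]),
            class = "gait_events")
}

#' Coerce a ground-truth event table to a `gait_events` object
#'
#' Keeps events inside `window` (if given), drops FCs outside the detected
#' IC span and reduces multiple FCs between two ICs to the first.
#'
#' @param events data frame with columns `event` (`"IC"`/`"FC"`), `time`,
#'   `foot`.
#' @param window optional `c(start, end)` time window (s).
#' @return A [gait_events()] object.
#' @export
as_gait_events <- function(events, window = NULL) {
  if (!is.null(window))
    events <- events[events$time >= window[1] & events$time <= window[2], ]
  ic <- sort(events$time[events$event == "IC"])
  fc <- sort(events$time[events$event == "FC"])
  if (length(ic) < 2L) stop_gaitssc("fewer than 2 ICs in the window")
  fc <- fc[fc > ic[1] & fc < ic[length(ic)]]
  slot <- findInterval(fc, ic)
  fc <- fc[!duplicated(slot)]
  first_foot <- events$foot[events$event == "IC"][order(events$time[events$event == "IC"])][1]
  gait_events(ic, fc, first_foot = first_foot %||% "F1")
}

# Derivative-of-Gaussian kernel (unit L1 mass of the underlying Gaussian),
# sigma in samples. Convolving a signal with this yields the smoothed
# derivative, the discrete analogue of a gauss1 continuous wavelet transform.
gauss_deriv_kernel <- function(sigma) {
  half <- max(4L, ceiling(4 * sigma))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  -x / sigma^2 * g
}

conv_same <- function(x, k) {
  half <- (length(k) - 1L) / 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + length(x))]
}

local_extrema <- function(x, minima = TRUE) {
  s <- if (minima) -x else x
  n <- length(s)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[s[i] > s[i - 1L] & s[i] >= s[i + 1L]]
}

# Dominant step frequency (Hz) from the periodogram of the (integrated,
# demeaned) vertical signal, restricted to a physiological band.
dominant_step_frequency <- function(x, fs, band = c(0.5, 3.5)) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[seq_len(floor(n / 2))]^2
  fr <- (seq_len(floor(n / 2)) - 1) * fs / n
  inband <- fr >= band[1] & fr <= band[2]
  if (!any(inband)) return(2)
  fr[inband][which.max(sp[inband])]
}

#' Detect gait events from the vertical trunk acceleration
#'
#' McCamley-style detector: the filtered, gravity-free vertical acceleration
#' is smoothed by cumulative-trapezoid integration (then demeaned); its
#' first derivative is taken with a Gaussian continuous-wavelet
#' (derivative-of-Gaussian) transform, whose local minima mark the initial
#' contacts; differentiating once more, the local maxima of the second
#' Gaussian-CWT derivative mark the final contacts. Candidate events are
#' gated by amplitude and by physiological step-interval bounds; ICs closer
#' than `min_step` are merged (the weaker dropped). Exactly one FC is kept
#' between consecutive ICs (the strongest peak; imputed at the median
#' IC-to-FC offset when no peak survives). Foot labels alternate from the
#' first detected IC.
#'
#' @param vertical_signal numeric gravity-free vertical acceleration (g),
#'   or an [acceleration_recording()] (its `vt` column is used).
#' @param sampling_rate Hz (taken from the recording when omitted).
#' @param wavelet_scale Gaussian kernel sd in seconds; `NULL` (default)
#'   auto-tunes to 0.12 of the dominant step period.
#' @param min_step,max_step physiological bounds on the step interval (s).
#' @param t0 time of the first sample (s), used for reported event times.
#' @return A [gait_events()] object.
#' @export
detect_gait_events <- function(vertical_signal, sampling_rate = NULL,
                               wavelet_scale = NULL, min_step = 0.25,
                               max_step = 2.0, t0 = NULL) {
  if (inherits(vertical_signal, "accel_recording")) {
    sampling_rate <- sampling_rate %||% sampling_rate(vertical_signal)
    t0 <- t0 %||% vertical_signal$t[1]
    vertical_signal <- vertical_signal$vt
  }
  if (is.null(sampling_rate)) stop_gaitssc("sampling_rate is required")
  t0 <- t0 %||% 0
  x <- as.numeric(vertical_signal)
  fs <- sampling_rate
  if (length(x) < fs) stop_gaitssc("insufficient strides: signal shorter than 1 s")

  s <- pracma::cumtrapz(x)[, 1] / fs
  s <- s - mean(s)
  fstep <- dominant_step_frequency(s, fs)
  sigma_s <- (wavelet_scale %||% (0.12 / fstep)) * fs
  k1 <- gauss_deriv_kernel(sigma_s)
  d1 <- conv_same(s, k1) * fs   # ~ Gaussian-smoothed acceleration
  d2 <- conv_same(d1, k1) * fs  # ~ smoothed jerk

  cand <- local_extrema(d1, minima = TRUE)
  cand <- cand[d1[cand] < mean(d1) - 0.5 * sd(d1)]
  # merge ICs violating the lower physiological bound: drop the shallower
  while (length(cand) >= 2L && min(diff(cand)) < min_step * fs) {
    i <- which.min(diff(cand))
    drop <- if (d1[cand[i]] <= d1[cand[i + 1]]) i + 1L else i
    cand <- cand[-drop]
  }
  if (length(cand) < 4L)
    stop_gaitssc("insufficient strides: %d initial contacts detected (need >= 4)",
                 length(cand))
  if (any(diff(cand) > max_step * fs))
    warning("step interval beyond ", max_step,
            " s detected; possible missed contacts", call. = FALSE)

  peaks <- local_extrema(d2, minima = FALSE)
  peaks <- peaks[d2[peaks] > mean(d2) + 0.5 * sd(d2)]
  fc_idx <- rep(NA_real_, length(cand) - 1L)
  for (i in seq_len(length(cand) - 1L)) {
    inb <- peaks[peaks > cand[i] & peaks < cand[i + 1]]
    if (length(inb)) fc_idx[i] <- inb[which.max(d2[inb])]
  }
  if (anyNA(fc_idx)) { # impute isolated misses at the median IC->FC offset
    off <- stats::median(fc_idx - cand[-length(cand)], na.rm = TRUE)
    if (!is.finite(off)) off <- 0.25 * stats::median(diff(cand))
    miss <- which(is.na(fc_idx))
    fc_idx[miss] <- pmin(cand[miss] + off, (cand[miss] + cand[miss + 1L]) / 2)
  }
  gait_events(t0 + (cand - 1) / fs, t0 + (fc_idx - 1) / fs)
}
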