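# Brute-force minimization of the penalized least-squares objective over a
# coefficient lattice (p <= 2 here), with the intercept profiled out
# analytically. Independent of the coordinate-descent implementation.
brute_force_enet <- function(X, y, lambda, gamma, lim = 2, step = 0.004) {
  gr <- seq(-lim, lim, by = step)
  if (ncol(X) == 1L) {
    obj <- vapply(gr, function(b1) {
      phi0 <- mean(y - X[, 1] * b1)
      enet_objective(X, y, phi0, b1, lambda, gamma)
    }, 0)
    return(min(obj))
  }
  # vectorized over the 2-D lattice: residual sums via linearity
  G <- expand.grid(b1 = gr, b2 = gr)
  eta <- outer(X[, 1], G$b1) + outer(X[, 2], G$b2)
  phi0 <- colMeans(y - eta)
  rss <- colSums((y - sweep(eta, 2, phi0, "+"))^2) / (2 * length(y))
  pen <- lambda * ((1 - gamma) * 0.5 * (G$b1^2 + G$b2^2) +
                     gamma * (abs(G$b1) + abs(G$b2)))
  min(rss + pen)
}

# Small two-class feature matrix with a known planted effect.
make_planted_data <- function(n0 = 30, n1 = 15, p = 20, planted = 1:2,
                              d = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n0 + n1) * p), n0 + n1, p)
  X[(n0 + 1):(n0 + n1), planted] <- X[(n0 + 1):(n0 + n1), planted] + d
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c("HE", "MCI-E"), c(n0, n1)))
}

# Synthetic walk plus the detected events of its two trimmed segments.
detect_on_synthetic <- function(profile, seed, distance = 20,
                                noise_sd = 0.01, sampling_rate = 100) {
  sim <- generate_acceleration(profile, distance = distance,
                               sampling_rate = sampling_rate, seed = seed,
                               noise_sd = noise_sd)
  rec <- gaitssc:::lowpass_recording(tilt_correct(sim$recording))
  segs <- split_segments(rec)
  list(sim = sim, segs = segs,
       events = lapply(segs, detect_gait_events))
}

# Match detected ICs one-to-one against ground truth inside an interior
# window (`margin` clear of the segment edges, where partial steps live).
match_ic <- function(detected, truth_times, seg, margin = 0.3) {
  win <- c(seg$t[1] + margin, seg$t[nrow(seg)] - margin)
  det <- detected$ic_times[detected$ic_times >= win[1] & detected$ic_times <= win[2]]
  tru <- truth_times[truth_times >= win[1] & truth_times <= win[2]]
  list(det = det, tru = tru,
       err = if (length(det)) vapply(det, function(x) min(abs(x - truth_times)), 0)
             else numeric(0))
}
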