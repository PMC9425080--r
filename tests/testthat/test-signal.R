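make_rec <- function(n = 500, fs = 100, ap = 0, ml = 0, vt = 1) {
  t <- (seq_len(n) - 1) / fs
  acceleration_recording(t, rep_len(ap, n), rep_len(ml, n), rep_len(vt, n), fs)
}

test_that("axis mapping is a signed permutation with the expected algebra", {
  rec <- make_rec(200)
  rec$ap <- rnorm(200); rec$ml <- rnorm(200); rec$vt <- 1 + rnorm(200, 0, 0.05)

  ident <- transform_axes(rec)
  expect_equal(ident$ap, rec$ap)
  expect_equal(ident$vt, rec$vt)

  m <- c(ap = "-y", ml = "+x", vt = "-z")
  twice <- transform_axes(transform_axes(rec, m), c(ap = "+y", ml = "-x", vt = "-z"))
  expect_equal(twice$ap, rec$ap)
  expect_equal(twice$ml, rec$ml)
  expect_equal(twice$vt, rec$vt)

  # device frame with gravity on -x: mapping it to vertical restores ~1 g
  dev <- data.frame(t = rec$t, ax = -1 + rnorm(200, 0, 0.01),
                    ay = rnorm(200, 0, 0.01), az = rnorm(200, 0, 0.01))
  vtrec <- transform_axes(dev, c(ap = "+z", ml = "+y", vt = "-x"),
                          sampling_rate = 100)
  expect_lt(abs(mean(vtrec$vt) - 1), 0.01)

  expect_error(transform_axes(rec, c(ap = "+x", ml = "+x", vt = "+z")),
               "signed permutation")
})

test_that("tilt correction levels a statically tilted recording", {
  rec <- make_rec(400)
  out <- tilt_correct(rec) # already level: vertical just loses gravity
  expect_equal(out$vt, rec$vt - 1, tolerance = 1e-12)

  # rotate a level gravity recording by 5 degrees about the ml axis
  th <- 5 * pi / 180
  tilted <- make_rec(400)
  tilted$ap <- sin(th) * 1; tilted$vt <- cos(th) * 1
  cor1 <- tilt_correct(tilted)
  expect_lt(abs(mean(cor1$ap)), 1e-6)
  expect_lt(abs(mean(cor1$ml)), 1e-6)
  expect_lt(abs(mean(cor1$vt)), 1e-6)

  # idempotence: correcting a corrected recording changes nothing
  cor2 <- tilt_correct(cor1)
  expect_equal(cor2$ap, cor1$ap, tolerance = 1e-8)
  expect_equal(cor2$vt, cor1$vt, tolerance = 1e-8)

  # a gravity-compensated recording whose restored mean still vanishes
  ff <- make_rec(400, vt = -1)
  attr(ff, "gravity_free") <- TRUE
  expect_error(tilt_correct(ff), "free fall")
})

test_that("zero-lag Butterworth filter has the expected passband behaviour", {
  fs <- 100; t <- seq(0, 10, by = 1 / fs)
  expect_equal(lowpass_filter(rep(2, 300), fs), rep(2, 300), tolerance = 1e-3)

  x10 <- sin(2 * pi * 10 * t)
  y10 <- lowpass_filter(x10, fs)
  expect_lt(max(abs(y10[200:800])), 0.01) # 10 Hz: > 40 dB down at 3 Hz cutoff

  x05 <- sin(2 * pi * 0.5 * t)
  y05 <- lowpass_filter(x05, fs)
  cc <- stats::ccf(y05[100:900], x05[100:900], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0) # zero phase shift

  expect_error(lowpass_filter(x05, fs, cutoff = 50), "Nyquist")
})

test_that("turn splitting cuts inside the true gap and trims 3 s per end", {
  pr <- gait_profile(0.5, 2, 0.2, 0.7)
  sim <- generate_acceleration(pr, distance = 20, seed = 4)
  rec <- gaitssc:::lowpass_recording(tilt_correct(sim$recording))
  segs <- split_segments(rec)
  split <- attr(segs, "split_time")
  expect_gt(split, sim$turn["start"])
  expect_lt(split, sim$turn["end"])
  # each retained segment loses exactly the 3 s margins
  expect_equal(segs[[1]]$t[1], rec$t[1] + 3, tolerance = 0.05)
  dur1 <- diff(range(segs[[1]]$t))
  expect_equal(dur1, split - rec$t[1] - 6, tolerance = 0.05)

  flat <- make_rec(2000, vt = 1 + 0.2 * sin(2 * pi * 2 * (1:2000) / 100))
  expect_error(split_segments(tilt_correct(flat)), "no turn detected")
  # a detectable gap whose flanking segments are shorter than 2 x trim
  short <- make_rec(650)
  tt <- short$t
  short$vt <- ifelse(tt < 2 | tt > 4, 0.3 * sin(2 * pi * 2 * tt), 0)
  expect_error(split_segments(short), "shorter than twice")
})

test_that("event detection recovers noise-free initial contacts within 30 ms", {
  pr <- gait_profile(0.5, 0, 0.2, 0.7)
  res <- detect_on_synthetic(pr, seed = 5, noise_sd = 0)
  truth <- res$sim$events$time[res$sim$events$event == "IC"]
  for (d in 1:2) {
    m <- match_ic(res$events[[d]], truth, res$segs[[d]])
    expect_equal(length(m$det), length(m$tru)) # count matches in the window
    expect_lt(mean(m$err) * 1000, 30)
  }
  expect_error(detect_gait_events(rep(0, 1000), 100), "insufficient strides")
})

test_that("detected step-time variability tracks the planted CoV within 1 pp", {
  for (step_time in c(0.4, 0.6, 0.8)) {
    pr <- gait_profile(step_time, 3, 0.2, step_time * 1.4, asymmetry_ratio = 1)
    pooled <- unlist(lapply(1:4, function(sd) {
      res <- detect_on_synthetic(pr, seed = sd, noise_sd = 0, distance = 30)
      unlist(lapply(res$events, function(ev) diff(ev$ic_times)))
    }))
    cov_hat <- 100 * sd(pooled) / mean(pooled)
    expect_lt(abs(cov_hat - 3), 1)
  }
})

test_that("detected events always satisfy the gait-event invariants", {
  for (seed in 1:5) {
    pr <- gait_profile(0.45 + 0.05 * seed, 4, 0.18, 0.6)
    res <- detect_on_synthetic(pr, seed = seed)
    for (ev in res$events) {
      expect_true(all(diff(ev$ic_times) > 0))
      expect_true(all(diff(ev$fc_times) > 0))
      expect_length(ev$fc_times, length(ev$ic_times) - 1L)
      expect_true(all(ev$fc_times > head(ev$ic_times, -1)))
      expect_true(all(ev$fc_times < tail(ev$ic_times, -1)))
      expect_true(all(ev$ic_foot[-1] != head(ev$ic_foot, -1)))
    }
  }
})

test_that("a time-reversed symmetric signal yields mirrored events", {
  pr <- gait_profile(0.5, 0, 0.2, 0.7)
  sim <- generate_acceleration(pr, distance = 15, seed = 6, noise_sd = 0)
  rec <- gaitssc:::lowpass_recording(tilt_correct(sim$recording))
  seg <- split_segments(rec)[[1]]
  fwd <- detect_gait_events(seg$vt, 100)
  rev_ev <- detect_gait_events(rev(seg$vt), 100)
  dur <- (length(seg$vt) - 1) / 100
  mirrored <- sort(dur - rev_ev$ic_times)
  common <- min(length(mirrored), length(fwd$ic_times))
  # compare interior events (edges may truncate one partial step)
  a <- fwd$ic_times[seq_len(common)]; b <- mirrored[seq_len(common)]
  expect_lt(median(abs(a - b)), 0.04)
})

test_that("the signal chain is deterministic end to end", {
  pr <- gait_profile(0.52, 2.5, 0.2, 0.68)
  run_once <- function() {
    sim <- generate_acceleration(pr, distance = 18, seed = 11)
    rec <- gaitssc:::lowpass_recording(tilt_correct(sim$recording))
    lapply(split_segments(rec), detect_gait_events)
  }
  expect_identical(run_once(), run_once())
})
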