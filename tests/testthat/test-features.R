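test_that("stride parameters follow the interval arithmetic of the gait cycle", {
  ev <- gait_events(c(0, 0.5, 1.0, 1.5), c(0.15, 0.65, 1.15))
  iv <- compute_stride_params(ev)
  expect_equal(iv$step_times, rep(0.5, 3))
  expect_equal(iv$stride_f1, 1.0)
  expect_equal(iv$stride_f2, 1.0)
  # stance: IC to the same foot's toe-off; swing: toe-off to its next IC
  expect_equal(iv$stance_f1, 0.65)
  expect_equal(iv$stance_f2, 0.65)
  expect_equal(as.numeric(iv$swing_f1[1]), 0.35)
  expect_equal(iv$double_support, rep(0.15, 3))
  expect_equal(iv$single_support, rep(0.35, 3))

  expect_error(gait_events(c(0, 0.4, 1.0), c(0.5, 0.9)),
               "strictly between")
  expect_error(compute_stride_params(gait_events(c(0, 0.5, 1.0), c(0.2, 0.7))),
               "at least 4")
})

test_that("per-foot series recover a planted asymmetric profile", {
  pr <- gait_profile(0.5, 0, 0.2, 0.7, asymmetry_ratio = 0.55 / 0.45 * 1)
  # asymmetry 1.222: foot means 0.55 and 0.45 s
  sim <- generate_acceleration(pr, distance = 25, seed = 3, noise_sd = 0)
  ev <- as_gait_events(sim$events, window = c(0, sim$turn["start"]))
  iv <- compute_stride_params(ev)
  m1 <- mean(iv$step_times[iv$step_foot == "F1"])
  m2 <- mean(iv$step_times[iv$step_foot == "F2"])
  expect_equal(sort(c(m1, m2)), c(0.45, 0.55), tolerance = 0.01)
  expect_equal(mean(c(iv$stride_f1, iv$stride_f2)), 1.0, tolerance = 0.01)
})

test_that("the sixteen STGF follow their closed-form definitions", {
  ev <- gait_events(seq(0, 5, by = 0.5), seq(0.15, 4.8, by = 0.5))
  iv <- compute_stride_params(ev)
  fs <- 100
  A <- 0.3
  vt <- A * sin(2 * pi * 2 * seq(0, 5, by = 1 / fs))
  st <- compute_stgf(iv, vt, sampling_rate = fs, height = 170)
  expect_equal(unname(st["StpT"]), 0.5)
  expect_equal(unname(st["StpTCoV"]), 0)
  expect_equal(unname(st["Cd"]), 120)
  expect_equal(unname(st["Cd"] * st["StpT"]), 60)
  expect_equal(unname(st["StrT"]), 1.0)
  expect_equal(unname(st["RMS"]), A / sqrt(2), tolerance = 1e-3)
  expect_equal(unname(st["DSD"]), 0.15)
  expect_equal(unname(st["SSD"]), 0.35)
  expect_equal(unname(st["StrT"]), unname(st["StepDurF1"] + st["StepDurF2"]),
               tolerance = 1e-9)

  # two-valued step series: mean 0.5, sample sd ~ 0.1414, CoV ~ 28.28 %
  iv2 <- list(step_times = c(0.4, 0.6, 0.4, 0.6), step_foot = c("F1", "F2", "F1", "F2"),
              stride_f1 = c(1, 1, 1), stride_f2 = c(1, 1, 1),
              stance_f1 = 0.6, stance_f2 = 0.6,
              swing_f1 = 0.4, swing_f2 = 0.4, double_support = 0.1,
              single_support = 0.4)
  st2 <- compute_stgf(iv2, vt, sampling_rate = fs, distance_walked = 2)
  expect_equal(unname(st2["StpT"]), 0.5)
  expect_equal(unname(st2["StpTCoV"]), 100 * sd(c(0.4, 0.6, 0.4, 0.6)) / 0.5,
               tolerance = 1e-6)

  expect_error(compute_stgf(list(step_times = c(0.5, 0.5)), vt,
                            sampling_rate = fs), "fewer than 3")
})

test_that("dual-task cost follows the signed percentage formula", {
  expect_equal(compute_dtc(1.0, 1.0), 0)
  expect_equal(compute_dtc(1.2, 0.9), 25)
  expect_equal(compute_dtc(1.0, 1.3), -30)
  expect_error(compute_dtc(0, 1), "zero")
  # linear in the dual value, zero at equality
  s <- 1.7
  d <- seq(0.5, 2, by = 0.25)
  expect_equal(compute_dtc(s, d), (s - d) / s * 100)
})

test_that("feature assembly yields 96 direction-averaged named columns", {
  mk_vec <- function(base) {
    v <- rep(base, 16)
    names(v) <- stgf_names()
    v
  }
  subj <- function(base) {
    tasks <- lapply(task_names(), function(tk) list(mk_vec(base), mk_vec(base + 1)))
    names(tasks) <- task_names()
    tasks
  }
  stgf <- list(S1 = subj(1), S2 = subj(2))
  ft <- assemble_feature_table(stgf)
  expect_equal(ncol(ft), 96L)
  expect_setequal(colnames(ft), feature_column_names())
  expect_equal(ft["S1", "NormalW::StpT"], 1.5) # mean of directions 1 and 2

  # dual-task-cost columns are computed per direction, then averaged
  s <- list(S1 = subj(1))
  s$S1$EasyD <- list(mk_vec(0.5), mk_vec(3))
  ft2 <- assemble_feature_table(s)
  expect_equal(ft2["S1", "dtc::EasyD::StpT"],
               mean(c((1 - 0.5) / 1, (2 - 3) / 2)) * 100)

  # two single tasks only: 32 columns and no DTC block
  ft3 <- assemble_feature_table(stgf, tasks = c("NormalW", "FastW"))
  expect_equal(ncol(ft3), 32L)
  expect_false(any(grepl("^dtc::", colnames(ft3))))

  # subjects with missing tasks are dropped with a reason
  broken <- stgf
  broken$S2$FastW <- NULL
  ft4 <- assemble_feature_table(broken)
  expect_equal(rownames(ft4), "S1")
  expect_match(attr(ft4, "dropped"), "S2")
})

test_that("model enumeration covers the eleven task subsets", {
  models <- enumerate_models()
  expect_length(models, 11L)
  expect_equal(sum(lengths(models) == 1), 4L) # single tasks
  expect_equal(sum(lengths(models) == 2), 6L) # pairs
  expect_equal(models[["All-tasks"]], task_names())

  co <- generate_cohort(cohort_spec(n_ya = 0, n_he = 8, n_mcie = 4, seed = 1))
  ft <- generate_feature_table(co, seed = 2)
  expect_equal(ncol(select_model_columns(ft, "NormalW")) - 2L, 16L)
  expect_equal(ncol(select_model_columns(ft, "EasyD+FastW")) - 2L, 48L)
  expect_equal(ncol(select_model_columns(ft, "NormalW+FastW")) - 2L, 32L)
  expect_equal(ncol(select_model_columns(ft, "All-tasks")) - 2L, 96L)
  expect_error(select_model_columns(ft, "SlowW"), "unknown model")
})

test_that("end-to-end extraction recovers the planted gait profile", {
  pr <- gait_profile(0.55, 3, 0.2, 0.7, asymmetry_ratio = 1)
  res <- detect_on_synthetic(pr, seed = 8, distance = 30)
  st <- compute_stgf(compute_stride_params(res$events[[1]]),
                     res$segs[[1]], height = 170)
  expect_lt(abs(st["StpT"] - 0.55), 0.01)
  expect_lt(abs(st["StpTCoV"] - 3), 1)
  expect_lt(abs(st["RMS"] - 0.2) / 0.2, 0.05)
  expect_equal(unname(st["Cd"] * st["StpT"]), 60)
  expect_equal(unname(st["StrT"]), unname(2 * st["StpT"]), tolerance = 0.02)
})
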