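test_that("cohort generation honours the spec counts and is deterministic", {
  co <- generate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(co), 125L)
  expect_equal(as.vector(table(co$group)), c(40L, 62L, 23L))
  expect_true(all(co$age[co$group == "YA"] >= 22 & co$age[co$group == "YA"] <= 38))
  expect_true(all(co$age[co$group != "YA"] >= 60))
  expect_identical(co, generate_cohort(cohort_spec(seed = 1)))
  expect_false(identical(co, generate_cohort(cohort_spec(seed = 2))))

  empty <- generate_cohort(cohort_spec(n_ya = 0, n_he = 0, n_mcie = 0))
  expect_equal(nrow(empty), 0L)
  expect_error(cohort_spec(n_ya = -1), "non-negative")
})

test_that("cognitive scores depend on group only through the planted shift", {
  co <- generate_cohort(cohort_spec(n_ya = 150, n_he = 150, n_mcie = 150,
                                    seed = 3))
  sc0 <- generate_cognitive_scores(co, effect = rep(0, 12),
                                   sigma = diag(12), seed = 4)
  # with zero effect, age/education-adjusted measure means match across groups
  d <- attr(sc0, "deficit")
  for (g in levels(co$group)) {
    mg <- colMeans(d[co$group == g, ])
    expect_true(all(abs(mg) < 3 / sqrt(sum(co$group == g))))
  }

  eff <- c(2, 1.5, 1, 0.5, 1, 2, 1.5, 0.5, 1, 1, 0.8, 1.2)
  co2 <- generate_cohort(cohort_spec(n_ya = 0, n_he = 1000, n_mcie = 1000,
                                     seed = 5))
  sc <- generate_cognitive_scores(co2, effect = eff, seed = 6)
  d2 <- attr(sc, "deficit")
  shift <- colMeans(d2[co2$group == "MCI-E", ]) - colMeans(d2[co2$group == "HE", ])
  se <- sqrt(2 * diag(default_score_covariance()) / 1000)
  expect_true(all(abs(shift - eff) < 3 * se))

  expect_identical(generate_cognitive_scores(co2, seed = 7),
                   generate_cognitive_scores(co2, seed = 7))
  expect_error(generate_cognitive_scores(co2, sigma = matrix(0, 12, 12)),
               "positive-definite")
})

test_that("acceleration generator plants step timing, CoV and RMS faithfully", {
  # zero variability: ground-truth ICs equally spaced at the step time
  pr0 <- gait_profile(0.5, 0, 0.2, 0.7, asymmetry_ratio = 1)
  sim0 <- generate_acceleration(pr0, distance = 15, seed = 1, noise_sd = 0)
  ic <- sim0$events$time[sim0$events$event == "IC"]
  d1 <- diff(ic[ic < sim0$turn["start"]])
  expect_true(all(abs(d1 - 0.5) < 1e-9))

  # planted CoV recovered from the ground-truth intervals at ~500 steps
  pr3 <- gait_profile(0.5, 3, 0.2, 0.7, asymmetry_ratio = 1)
  sim3 <- generate_acceleration(pr3, distance = 180, seed = 2)
  ic3 <- sim3$events$time[sim3$events$event == "IC"]
  steps <- c(diff(ic3[ic3 < sim3$turn["start"]]),
             diff(ic3[ic3 > sim3$turn["end"]]))
  expect_gt(length(steps), 450)
  expect_lt(abs(100 * sd(steps) / mean(steps) - 3), 1)

  # determinism and the sizing error
  s1 <- generate_acceleration(pr3, distance = 15, seed = 9)
  s2 <- generate_acceleration(pr3, distance = 15, seed = 9)
  expect_identical(s1, s2)
  expect_error(generate_acceleration(pr0, distance = 1, seed = 1), "trim margin")
})

test_that("ground-truth event lists satisfy the gait-cycle invariants", {
  for (seed in 1:3) {
    pr <- gait_profile(0.55, 4, 0.2, 0.65, asymmetry_ratio = 1.05,
                       double_support_frac = 0.14)
    sim <- generate_acceleration(pr, distance = 20, seed = seed)
    ev <- sim$events
    expect_true(all(diff(ev$time[ev$event == "IC"]) > 0))
    expect_true(all(diff(ev$time[ev$event == "FC"]) > 0))
    # each FC lies strictly between its foot's IC and that foot's next IC
    for (f in c("F1", "F2")) {
      ics <- ev$time[ev$event == "IC" & ev$foot == f]
      fcs <- ev$time[ev$event == "FC" & ev$foot == f]
      for (x in fcs) {
        before <- ics[ics < x]
        after <- ics[ics > x]
        # the first FC of a foot precedes its first IC (stance from standing)
        if (length(before)) expect_gt(x, max(before))
        if (length(before) && length(after)) expect_lt(x, min(after))
      }
    }
  }
})

test_that("direct feature tables carry the requested null or planted effects", {
  co <- generate_cohort(cohort_spec(n_ya = 0, n_he = 200, n_mcie = 200, seed = 1))
  ft0 <- generate_feature_table(co, effect_size = 0, seed = 2)
  X <- as.matrix(ft0[, -(1:2)])
  tt <- apply(X, 2, function(v)
    t.test(v[ft0$group == "HE"], v[ft0$group == "MCI-E"])$statistic)
  expect_lt(mean(abs(tt) > 1.96), 0.12) # ~5% under the null

  ft <- generate_feature_table(co, planted_features = 7L, effect_size = 10,
                               seed = 3)
  auc <- auc <- gaitssc:::auc_rank(ft[[7 + 2]], ft$group == "MCI-E")
  expect_gt(auc, 0.999)

  expect_identical(generate_feature_table(co, seed = 5),
                   generate_feature_table(co, seed = 5))
  expect_error(generate_feature_table(co, planted_features = 97), "1..96")
})

test_that("synthetic scores reproduce the target MDCog group structure", {
  co <- generate_cohort(cohort_spec(seed = 21))
  nm <- generate_normative_scores(400, seed = 22)
  sc <- generate_cognitive_scores(co, seed = 23)
  model <- fit_normative_model(nm)
  md <- compute_mdcog(sc, model)
  targets <- c(YA = 2.91, HE = 3.81, "MCI-E" = 9.30)
  for (g in names(targets)) {
    x <- md[co$group == g]
    expect_lt(abs(mean(x) - targets[[g]]), 3 * sd(x) / sqrt(length(x)))
  }
})
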