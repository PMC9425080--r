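test_that("stability selection recovers planted biomarkers and rejects noise", {
  co <- generate_cohort(cohort_spec(n_ya = 0, seed = 1)) # 62 HE / 23 MCI-E
  planted <- c(5L, 20L, 70L)
  ft <- generate_feature_table(co, planted_features = planted,
                               effect_size = 2, seed = 2)
  X <- as.matrix(ft[, -(1:2)])
  st <- stability_selection(X, ft$group, n_iter = 100, seed = 3)
  expect_true(all(st$frequency[planted] > 0.5))
  expect_setequal(st$stable, names(st$frequency)[st$frequency > 0.5])
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  expect_lt(median(st$frequency[-planted]), min(st$frequency[planted]))

  # pure noise: the stable set is (near) empty
  ft0 <- generate_feature_table(co, effect_size = 0, seed = 4)
  st0 <- stability_selection(as.matrix(ft0[, -(1:2)]), ft0$group,
                             n_iter = 100, seed = 5)
  expect_lte(length(st0$stable), 2L)

  # determinism under a fixed seed
  st2 <- stability_selection(X, ft$group, n_iter = 25, seed = 9)
  st3 <- stability_selection(X, ft$group, n_iter = 25, seed = 9)
  expect_identical(st2, st3)

  # a single iteration can only produce frequencies of zero or one
  st1 <- stability_selection(X[, 1:10], ft$group, n_iter = 1, seed = 6)
  expect_true(all(st1$frequency %in% c(0, 1)))
})

test_that("selection power grows with the planted effect size", {
  co <- generate_cohort(cohort_spec(n_ya = 0, seed = 11))
  planted <- c(10L, 40L, 80L)
  min_freq <- vapply(c(0.5, 1.25, 2.5), function(d) {
    ft <- generate_feature_table(co, planted_features = planted,
                                 effect_size = d, seed = 12)
    st <- stability_selection(as.matrix(ft[, -(1:2)]), ft$group,
                              n_iter = 60, seed = 13)
    min(st$frequency[planted])
  }, 0)
  expect_true(all(diff(min_freq) >= -0.05)) # monotone up to resampling noise
  expect_gt(min_freq[3], min_freq[1])
})

test_that("validation yields calibrated AUC distributions", {
  co <- generate_cohort(cohort_spec(n_ya = 0, seed = 21))
  ft <- generate_feature_table(co, planted_features = 1:3,
                               effect_size = 6, seed = 22)
  X <- as.matrix(ft[, 3:8]) # includes the three planted columns

  # near-perfect separation gives a median AUC of 1
  vr <- validate_model(X, ft$group, n_iter = 50, seed = 23)
  expect_equal(vr$median_auc, 1, tolerance = 0.01)
  expect_true(all(vr$auc >= 0 & vr$auc <= 1, na.rm = TRUE))
  expect_equal(vr$median_auc, unname(quantile(vr$auc, 0.5, na.rm = TRUE)),
               tolerance = 1e-9)

  # permuted labels give a null distribution centered at one half
  set.seed(24)
  yperm <- sample(as.character(ft$group))
  vr0 <- validate_model(X, yperm, n_iter = 100, seed = 25)
  expect_gt(vr0$median_auc, 0.4)
  expect_lt(vr0$median_auc, 0.6)

  # fixed seed reproduces the AUC sample exactly
  va <- validate_model(X, ft$group, n_iter = 20, seed = 26)
  vb <- validate_model(X, ft$group, n_iter = 20, seed = 26)
  expect_identical(va$auc, vb$auc)

  # empty stable set is an explicit result, not an exception
  v_empty <- validate_model(X[, 0], ft$group, n_iter = 5, seed = 27)
  expect_true(v_empty$no_biomarkers)
  expect_true(is.na(v_empty$median_auc))
})

test_that("the rank-based AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (r in 1:5) {
    sc <- rnorm(60) + rep(c(0, 0.8), c(35, 25))
    pos <- rep(c(FALSE, TRUE), c(35, 25))
    ref <- as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(gaitssc:::auc_rank(sc, pos), ref, tolerance = 1e-12)
  }
  # ties are handled as half-credit, matching the trapezoidal ROC area
  sc_t <- c(1, 1, 2, 2, 3)
  pos_t <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  ref_t <- as.numeric(pROC::auc(pROC::roc(pos_t, sc_t, quiet = TRUE,
                                          direction = "<")))
  expect_equal(gaitssc:::auc_rank(sc_t, pos_t), ref_t)
})

test_that("the operating point honours the target sensitivity", {
  vr <- structure(list(no_biomarkers = FALSE,
                       scores = c(rnorm(200, 3), rnorm(400, -3)),
                       labels = rep(c(1, 0), c(200, 400))),
                  class = "validation_result")
  op <- operating_point(vr, 0.90)
  expect_gte(op$sensitivity, 0.90)
  expect_equal(op$specificity, 1, tolerance = 0.01) # separated classes
  expect_true(op$target_attained)

  set.seed(1)
  vr_rand <- structure(list(no_biomarkers = FALSE, scores = runif(4000),
                            labels = rep(c(1, 0), 2000)),
                       class = "validation_result")
  op_r <- operating_point(vr_rand, 0.90)
  expect_gte(op_r$sensitivity, 0.90)
  expect_lt(abs(op_r$specificity - 0.10), 0.04) # ROC diagonal

  vr_deg <- structure(list(no_biomarkers = FALSE, scores = rep(1, 100),
                           labels = rep(c(1, 0), 50)),
                      class = "validation_result")
  op_d <- operating_point(vr_deg, 0.90)
  expect_false(op_d$target_attained)
  expect_equal(op_d$sensitivity, 1)
})
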