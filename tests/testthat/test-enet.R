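test_that("the elastic-net penalty evaluates its closed forms", {
  expect_equal(penalty(c(1, -2), 1), 3)
  expect_equal(penalty(c(1, -2), 0), 2.5)
  expect_equal(penalty(c(1, -2), 0.5), 2.75)
  expect_error(penalty(c(1, 2), 1.5), "gamma")
})

test_that("coordinate descent matches the brute-force oracle on tiny problems", {
  set.seed(7)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n) + X[, 1]
  for (gam in c(0, 0.3, 0.7, 1)) {
    for (lam in c(0.05, 0.3)) {
      fit <- elastic_net_fit(X, y, lam, enet_config(gamma = gam))
      oracle <- brute_force_enet(X, y, lam, gam)
      expect_lt(abs(fit$objective - oracle), 1e-4)
      expect_lte(fit$objective, oracle + 1e-8) # the lattice never beats CD
    }
  }
  # single-feature problems against a fine one-dimensional lattice
  X1 <- matrix(rnorm(n), n, 1)
  y1 <- 0.8 * X1[, 1] + rnorm(n, 0, 0.5)
  f1 <- elastic_net_fit(X1, y1, 0.2, enet_config(gamma = 0.5))
  expect_lt(abs(f1$objective - brute_force_enet(X1, y1, 0.2, 0.5)), 1e-4)
})

test_that("the lasso solution on an orthonormal design is soft thresholding", {
  set.seed(8)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  X <- Q * sqrt(n) # columns centered? enforce: orthonormal after centering
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- qr.Q(qr(X)) * sqrt(n)
  y <- rnorm(n) + 0.9 * X[, 1] - 0.4 * X[, 2]
  ols <- crossprod(X, y - mean(y)) / n
  for (lam in c(0.05, 0.2, 0.6)) {
    fit <- elastic_net_fit(X, y, lam, enet_config(gamma = 1))
    expected <- sign(ols) * pmax(abs(ols) - lam, 0)
    expect_equal(fit$coefficients, as.numeric(expected), tolerance = 1e-6)
  }
})

test_that("the regularization path starts empty and ends near least squares", {
  set.seed(9)
  n <- 50; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% c(1, -0.5, rep(0, p - 2)) + rnorm(n, 0, 0.3)
  cfg <- enet_config(gamma = 0.5)
  lmax <- lambda_max(X, y, 0.5)
  f0 <- elastic_net_fit(X, y, lmax * 1.001, cfg)
  expect_true(all(f0$coefficients == 0))
  expect_equal(f0$intercept, mean(y))

  # gamma = 0, lambda -> 0 approaches ordinary least squares
  f_ridge <- elastic_net_fit(X, y, 1e-8, enet_config(gamma = 0))
  ls <- lm.fit(cbind(1, X), as.numeric(y))$coefficients
  expect_equal(f_ridge$coefficients, unname(ls[-1]), tolerance = 1e-4)

  # warm-started path is continuous in lambda
  path <- elastic_net_fit(X, y, exp(seq(log(lmax), log(lmax * 1e-3),
                                        length.out = 60)), cfg)
  jumps <- apply(abs(diff(t(path$coefficients))), 1, max)
  expect_lt(max(jumps), 0.12)

  expect_error(elastic_net_fit(X, c(y[-1], NA), 0.1, cfg), "non-finite")
  expect_error(elastic_net_fit(X, y, -1, cfg), "positive")
})

test_that("coordinate descent agrees with an independent library solver", {
  skip_if_not_installed("glmnet")
  set.seed(10)
  n <- 70; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.5) + 0.4 * X[, 3]
  for (gam in c(0.3, 0.5, 1)) {
    lam <- 0.08
    mine <- elastic_net_fit(X, y, lam, enet_config(gamma = gam))
    ref <- glmnet::glmnet(X, y, alpha = gam, lambda = lam,
                          standardize = FALSE, thresh = 1e-14)
    obj_ref <- enet_objective(X, y, as.numeric(ref$a0),
                              as.numeric(ref$beta), lam, gam)
    expect_lte(mine$objective, obj_ref + 1e-6)
    expect_lt(max(abs(mine$coefficients - as.numeric(ref$beta))), 2e-2)
  }
})

test_that("the optional logistic loss decreases its own objective to a sparse fit", {
  set.seed(11)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6)
  y <- as.numeric(runif(n) < plogis(1.5 * X[, 1]))
  cfg <- enet_config(gamma = 0.8, loss = "logistic", tol = 1e-8)
  f_tight <- elastic_net_fit(X, y, 0.02, cfg)
  f_loose <- elastic_net_fit(X, y, 0.4, cfg)
  expect_gt(abs(f_tight$coefficients[1]), 0.2) # signal feature survives
  expect_true(all(abs(f_loose$coefficients) <= abs(f_tight$coefficients) + 1e-6))
  # the reported objective is the logistic one and beats the zero model
  null_obj <- mean(log1p(exp(qlogis(mean(y)))) - y * qlogis(mean(y))) +
    0.02 * penalty(rep(0, 6), 0.8)
  expect_lt(f_tight$objective, null_obj + log(2))
})

test_that("cross-validated lambda selection behaves at the signal extremes", {
  set.seed(12)
  n <- 60; p <- 10
  cfg <- enet_config(n_folds = 5)
  # pure noise: the chosen lambda stays in the top of the path
  hits <- vapply(1:10, function(r) {
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(0:1, each = n / 2)
    cv <- cv_select_lambda(X, sample(y), cfg)
    cv$lambda >= quantile(cv$lambdas, 0.5)
  }, TRUE)
  expect_gte(mean(hits), 0.7)

  # one dominant feature: its coefficient is active at the chosen lambda
  active <- vapply(1:10, function(r) {
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(0:1, each = n / 2)
    X[, 4] <- X[, 4] + 2.5 * y
    cv <- cv_select_lambda(X, y, cfg)
    fit <- elastic_net_fit(X, y, cv$lambda, cfg)
    fit$coefficients[4] != 0
  }, TRUE)
  expect_gte(mean(active), 0.9)

  set.seed(33)
  X <- matrix(rnorm(n * p), n, p); y <- rep(0:1, each = n / 2)
  set.seed(44); l1 <- cv_select_lambda(X, y, cfg)$lambda
  set.seed(44); l2 <- cv_select_lambda(X, y, cfg)$lambda
  expect_identical(l1, l2)
})

test_that("screening keeps strong features and ranks degenerate ones last", {
  d <- make_planted_data(n0 = 40, n1 = 20, p = 10, planted = 3, d = 5, seed = 2)
  expect_identical(screen_features(d$X, d$y, 1), 1:10)
  kept <- screen_features(d$X, d$y, 0.5)
  expect_length(kept, 5L)
  expect_true(3L %in% kept)
  Xz <- d$X; Xz[, 7] <- 1 # constant feature
  expect_false(7L %in% screen_features(Xz, d$y, 0.5))
  expect_error(screen_features(d$X, d$y, 0), "keep_fraction")
})
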