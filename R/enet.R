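#' Elastic-net mixing penalty
#'
#' `P(phi) = (1 - gamma) * 0.5 * ||phi||_2^2 + gamma * ||phi||_1`. At
#' `gamma = 1` this is the lasso penalty, at `gamma = 0` the ridge penalty.
#'
#' @param phi coefficient vector.
#' @param gamma mixing parameter in `[0, 1]`.
#' @return Penalty value (scalar).
#' @export
penalty <- function(phi, gamma) {
  check_number(gamma, "gamma", 0, 1)
  (1 - gamma) * 0.5 * sum(phi^2) + gamma * sum(abs(phi))
}

#' Elastic-net objective function
#'
#' `(1/2N) sum_i (y_i - phi0 - x_i' phi)^2 + lambda * P_gamma(phi)`; the
#' quantity [elastic_net_fit()] minimizes.
#'
#' @param X n x p design matrix.
#' @param y response (group labels coded numerically for classification).
#' @param phi0 intercept.
#' @param phi coefficient vector.
#' @param lambda regularization strength (> 0).
#' @param gamma mixing parameter.
#' @return Objective value (scalar).
#' @export
enet_objective <- function(X, y, phi0, phi, lambda, gamma) {
  r <- y - phi0 - as.numeric(X %*% phi)
  sum(r^2) / (2 * length(y)) + lambda * penalty(phi, gamma)
}

#' Configuration of the elastic-net / SSC machinery
#'
#' @param gamma mixing parameter in `[0, 1]` (0.5 blends ridge and lasso
#'   evenly).
#' @param nlambda,lambda_min_ratio regularization path: `nlambda`
#'   log-spaced values from the smallest all-zero lambda down to
#'   `lambda_min_ratio` times it.
#' @param n_folds folds of the internal cross-validation.
#' @param one_se use the one-standard-error rule instead of the CV minimum.
#' @param standardize z-score features with training-portion statistics
#'   inside every resample.
#' @param loss `"squared"` fits the printed linear-regression form on 0/1
#'   labels; `"logistic"` is an optional comparison variant.
#' @param tol,maxit coordinate-descent convergence control; `tol` bounds
#'   the per-update objective change relative to the null variance.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(gamma = 0.5, nlambda = 100L, lambda_min_ratio = 1e-3,
                        n_folds = 10L, one_se = FALSE, standardize = TRUE,
                        loss = c("squared", "logistic"),
                        tol = 1e-7, maxit = 100000L) {
  check_number(gamma, "gamma", 0, 1)
  loss <- match.arg(loss)
  structure(list(gamma = gamma, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = as.integer(n_folds), one_se = one_se,
                 standardize = standardize, loss = loss,
                 tol = tol, maxit = as.integer(maxit)),
            class = "enet_config")
}

#' Smallest lambda with an all-zero solution
#'
#' Entry point of the regularization path: `max_j |x_j' (y - ybar)| / (N
#' gamma)` on centered data (gamma floored at 0.001 so the ridge end of the
#' mixing range still yields a finite path).
#'
#' @inheritParams enet_objective
#' @param gamma mixing parameter.
#' @return Positive scalar.
#' @export
lambda_max <- function(X, y, gamma) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  max(abs(crossprod(Xc, y - mean(y)))) / (length(y) * max(gamma, 1e-3))
}

# Decreasing log-spaced lambda grid from lambda_max.
lambda_grid <- function(X, y, config) {
  lmax <- lambda_max(X, y, config$gamma)
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$nlambda))
}

#' Fit the elastic net by cyclic coordinate descent
#'
#' Minimizes the penalized squared-error objective (see
#' [enet_objective()]) by cyclic coordinate descent with soft-thresholding
#' updates and warm starts along a decreasing lambda path; a sweep stops
#' iterating when no single coefficient update changes the objective by
#' more than `config$tol` times the null variance of `y` — the
#' convergence semantics of the reference library implementations, robust
#' to weight shuffling between near-collinear features. `X` and `y` are
#' used as given — standardize beforehand if required.
#'
#' @inheritParams enet_objective
#' @param lambda a single value or decreasing path of positive values.
#' @param config an [enet_config()] (supplies `gamma`, `tol`, `maxit`).
#' @return For a single lambda, a list of class `enet_fit` with `intercept`,
#'   `coefficients`, `lambda`, `gamma`, `objective`, `iterations`, `n`,
#'   `p`; for a path, a list of class `enet_path` whose `coefficients` is a
#'   p x nlambda matrix.
#' @export
elastic_net_fit <- function(X, y, lambda, config = enet_config()) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_gaitssc("non-finite entries in X or y")
  if (length(y) != nrow(X)) stop_gaitssc("X and y dimensions disagree")
  if (any(lambda <= 0)) stop_gaitssc("lambda must be positive")
  if (length(lambda) > 1 && any(diff(lambda) > 0))
    stop_gaitssc("a lambda path must be decreasing")
  fit <- if (config$loss == "logistic")
    logistic_enet_path(X, as.numeric(y), as.numeric(lambda), config)
  else
    .enet_cd_path(X, as.numeric(y), as.numeric(lambda),
                  config$gamma, config$tol, config$maxit)
  if (length(lambda) == 1L) {
    phi <- fit$coefficients[, 1]
    obj <- if (config$loss == "logistic") {
      eta <- fit$intercepts[1] + as.numeric(X %*% phi)
      mean(log1p(exp(eta)) - y * eta) + lambda * penalty(phi, config$gamma)
    } else {
      enet_objective(X, y, fit$intercepts[1], phi, lambda, config$gamma)
    }
    structure(list(intercept = fit$intercepts[1], coefficients = phi,
                   lambda = lambda, gamma = config$gamma,
                   objective = obj,
                   iterations = fit$iterations[1],
                   n = nrow(X), p = ncol(X)),
              class = "enet_fit")
  } else {
    structure(list(intercepts = fit$intercepts, coefficients = fit$coefficients,
                   lambda = lambda, gamma = config$gamma,
                   iterations = fit$iterations, n = nrow(X), p = ncol(X)),
              class = "enet_path")
  }
}

# Optional logistic-loss variant, for comparison with the printed
# squared-error form: mean logistic deviance + lambda * P_gamma(phi),
# minimized by proximal gradient (FISTA) with warm starts along the path.
# Labels are expected in {0, 1}.
logistic_enet_path <- function(X, y, lambdas, config) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(1, X)
  L <- norm(Xi, "2")^2 / (4 * n) # Lipschitz bound of the logistic gradient
  beta <- rep(0, p + 1L)
  coefs <- matrix(0, p, length(lambdas))
  intercepts <- numeric(length(lambdas))
  iters <- integer(length(lambdas))
  for (l in seq_along(lambdas)) {
    lam <- lambdas[l]
    zb <- beta; tk <- 1
    for (it in seq_len(config$maxit)) {
      eta <- as.numeric(Xi %*% zb)
      grad <- crossprod(Xi, 1 / (1 + exp(-eta)) - y) / n
      u <- zb - grad / L
      new <- u
      s1 <- lam * config$gamma / L
      s2 <- lam * (1 - config$gamma) / L
      new[-1] <- sign(u[-1]) * pmax(abs(u[-1]) - s1, 0) / (1 + s2)
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      zb <- new + (tk - 1) / tn * (new - beta)
      delta <- max(abs(new - beta))
      beta <- new; tk <- tn
      if (delta < max(config$tol, 1e-9)) break
    }
    iters[l] <- it
    intercepts[l] <- beta[1]
    coefs[, l] <- beta[-1]
  }
  list(coefficients = coefs, intercepts = intercepts, iterations = iters)
}

#' Select lambda by stratified cross-validation
#'
#' Fits the full warm-started lambda path on each training fold and scores
#' mean squared prediction error on the held-out fold; returns the lambda
#' minimizing the mean CV error (or the largest lambda within one standard
#' error of it when `config$one_se`). Folds are stratified by class so
#' every fold sees both labels.
#'
#' @inheritParams enet_objective
#' @param config an [enet_config()].
#' @param lambdas optional decreasing path (defaults to the standard grid).
#' @return A list: `lambda` (chosen), `lambdas`, `cvm`, `cvsd`.
#' @export
cv_select_lambda <- function(X, y, config = enet_config(), lambdas = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- config$n_folds
  if (n < 2 * k) stop_gaitssc("need at least %d subjects for %d-fold CV", 2 * k, k)
  lambdas <- lambdas %||% lambda_grid(X, y, config)
  fold <- stratified_folds(y, k)
  err <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 1L) next
    fit <- elastic_net_fit(X[tr, , drop = FALSE], y[tr], lambdas, config)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$coefficients, 2,
                  fit$intercepts, "+")
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(err, na.rm = TRUE)
  cvsd <- apply(err, 2, sd, na.rm = TRUE) / sqrt(k)
  best <- which.min(cvm)
  chosen <- if (config$one_se)
    min(which(cvm <= cvm[best] + cvsd[best])) else best
  list(lambda = lambdas[chosen], lambdas = lambdas, cvm = cvm, cvsd = cvsd)
}

#' Univariate screening of features
#'
#' Ranks features by the absolute two-sample t statistic between classes
#' and keeps the top fraction; zero-variance features rank last. A cheap
#' filter that removes variables with minimal discriminative contribution
#' before the penalized fit.
#'
#' @inheritParams enet_objective
#' @param keep_fraction fraction of features retained, in (0, 1].
#' @return Sorted integer indices of the retained features.
#' @export
screen_features <- function(X, y, keep_fraction = 0.5) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_gaitssc("keep_fraction must lie in (0, 1]")
  X <- as.matrix(X)
  cls <- unique(y)
  if (length(cls) != 2L) stop_gaitssc("screening needs exactly two classes")
  a <- X[y == cls[1], , drop = FALSE]
  b <- X[y == cls[2], , drop = FALSE]
  se <- sqrt(apply(a, 2, var) / nrow(a) + apply(b, 2, var) / nrow(b))
  tstat <- abs(colMeans(a) - colMeans(b)) / se
  tstat[!is.finite(tstat)] <- -Inf # zero-variance features rank last
  keep <- max(1L, round(keep_fraction * ncol(X)))
  sort(order(tstat, decreasing = TRUE)[seq_len(keep)])
}
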