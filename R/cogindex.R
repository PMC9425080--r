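#' Fit the normative model behind the MDCog index
#'
#' Each of the twelve cognitive measures is first oriented so that higher
#' values mean better performance (timed measures are negated), then
#' regressed linearly on age and education over the normative sample. The
#' 12 x 12 covariance of the pooled residuals captures the correlation
#' between tests; when ill-conditioned (condition number above `cond_max`)
#' it is shrunk toward its diagonal with an analytic Schafer-Strimmer
#' intensity.
#'
#' @param normative_scores a data frame with `age`, `education` and the 12
#'   measure columns of [cognitive_measure_info()] (e.g. from
#'   [generate_normative_scores()]); >= 30 rows.
#' @param cond_max condition-number threshold that triggers shrinkage.
#' @return An object of class `normative_model`: per-measure coefficients,
#'   orientation flags, residual covariance and its inverse.
#' @export
fit_normative_model <- function(normative_scores, cond_max = 1e6) {
  info <- cognitive_measure_info()
  miss <- setdiff(info$measure, names(normative_scores))
  if (length(miss)) stop_gaitssc("missing measure columns: %s",
                                 paste(miss, collapse = ", "))
  n <- nrow(normative_scores)
  if (n < 30L) stop_gaitssc("need at least 30 normative subjects")
  X <- cbind(1, normative_scores$age, normative_scores$education)
  if (qr(X)$rank < 3L)
    stop_gaitssc("singular design: age and education must both vary")

  Y <- as.matrix(normative_scores[, info$measure]) %*% diag(info$orientation)
  colnames(Y) <- info$measure
  B <- qr.solve(X, Y) # 3 x 12: intercept, age, education per measure
  resid <- Y - X %*% B
  S <- crossprod(resid) / (n - 3)

  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  shrunk <- FALSE
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_max) {
    lambda <- shrinkage_intensity(resid)
    S <- (1 - lambda) * S + lambda * diag(diag(S))
    shrunk <- TRUE
  }
  structure(list(coefficients = B, orientation = info$orientation,
                 measures = info$measure, sigma = S, sigma_inv = solve(S),
                 n = n, shrunk = shrunk),
            class = "normative_model")
}

# Schafer-Strimmer analytic shrinkage intensity toward the diagonal target:
# lambda = sum of estimated variances of off-diagonal covariances over the
# sum of their squares, clamped to [0, 1]. With w_kij = xc_ki * xc_kj the
# variance needs only sum(w) = (n-1) S and sum(w^2) = (xc^2)' (xc^2), so
# everything reduces to two cross-products.
shrinkage_intensity <- function(resid) {
  n <- nrow(resid)
  xc <- scale(resid, center = TRUE, scale = FALSE)
  S <- crossprod(xc) / (n - 1)
  W2 <- crossprod(xc^2)
  var_s <- n / ((n - 1)^3) * (W2 - ((n - 1) * S)^2 / n)
  off <- upper.tri(S) | lower.tri(S)
  min(1, max(0, sum(var_s[off]) / sum(S[off]^2)))
}

#' Compute the MDCog summary cognitive index
#'
#' Mahalanobis distance of a subject's age/education-adjusted, orientation-
#' aligned cognitive residual vector from the normative data:
#' `MDCog = sqrt(r' Sigma^-1 r)`, where r is the deficit vector (predicted
#' minus observed performance, so larger = worse) and Sigma the normative
#' residual covariance. Larger MDCog means a performance profile further
#' below the age/education norm.
#'
#' @param scores data frame with `age`, `education` and the 12 measures
#'   (one row per subject).
#' @param model a [fit_normative_model()] object.
#' @return Numeric vector of non-negative MDCog values, one per row.
#' @export
compute_mdcog <- function(scores, model) {
  stopifnot(inherits(model, "normative_model"))
  miss <- setdiff(model$measures, names(scores))
  if (length(miss)) stop_gaitssc("missing measure columns: %s",
                                 paste(miss, collapse = ", "))
  X <- cbind(1, scores$age, scores$education)
  Y <- as.matrix(scores[, model$measures]) %*% diag(model$orientation)
  deficit <- X %*% model$coefficients - Y # predicted minus observed: worse > 0
  sqrt(pmax(rowSums((deficit %*% model$sigma_inv) * deficit), 0))
}

#' Define YA / HE / MCI-E groups from MDCog and age
#'
#' One-dimensional k-means on the MDCog values (k = 2, many random
#' restarts keeping the lowest within-cluster sum of squares) separates a
#' healthy from an impaired cluster (the higher-centroid cluster is
#' impaired, labeled MCI-E); the healthy cluster is split by age into
#' young adults (below `age_threshold`) and healthy elderly.
#'
#' @param mdcog numeric MDCog values.
#' @param ages ages (years), same length.
#' @param k number of clusters (2).
#' @param repeats random restarts of k-means.
#' @param age_threshold elderly age cut (years).
#' @param seed integer seed making the restarts reproducible.
#' @return A list of class `group_labels`: `group` (factor YA/HE/MCI-E
#'   aligned to the input order), `centers` (sorted centroids), `boundary`
#'   (decision cut between the two centroids), `totss`/`tot.withinss`
#'   clustering metadata.
#' @export
cluster_groups <- function(mdcog, ages, k = 2L, repeats = 1000L,
                           age_threshold = 60, seed = 1L) {
  if (length(mdcog) != length(ages)) stop_gaitssc("mdcog and ages differ in length")
  if (length(unique(mdcog)) < k)
    stop_gaitssc("need at least %d distinct MDCog values", k)
  set.seed(seed)
  km <- kmeans(matrix(mdcog, ncol = 1), centers = k, nstart = repeats)
  impaired <- which.max(km$centers[, 1])
  group <- ifelse(km$cluster == impaired, "MCI-E",
                  ifelse(ages < age_threshold, "YA", "HE"))
  centers <- sort(km$centers[, 1])
  structure(list(group = factor(group, levels = c("YA", "HE", "MCI-E")),
                 centers = centers,
                 boundary = mean(centers[(k - 1):k]),
                 tot_withinss = km$tot.withinss, repeats = repeats),
            class = "group_labels")
}
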