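#' Metadata for the twelve cognitive test measures
#'
#' Five neuropsychological tests yield twelve measures: global cognition
#' (MMSE and its recall item), auditory divided attention (BTA total and its
#' number/letter subscores), Trail Making Test parts A and B (completion
#' times, lower is better), Hopkins Verbal Learning Test (immediate, delayed,
#' retention) and Digit Symbol substitution (total and incidental recall).
#' For each measure the table holds a plausible linear dependence on age and
#' education, a residual scale, and an orientation flag (+1 when a higher
#' raw score means better performance, -1 for the timed measures).
#'
#' @return A data frame with columns `measure`, `b0`, `b_age`, `b_edu`,
#'   `sigma`, `orientation`.
#' @export
cognitive_measure_info <- function() {
  data.frame(
    measure = c("MMSE", "MMSE_recall", "BTA", "BTA_numbers", "BTA_letters",
                "TMT_A", "TMT_B", "HVLT_imm", "HVLT_del", "HVLT_ret",
                "DS", "DS_incidental"),
    b0    = c(26,  2.6, 15,  8,    8,    20,  45,  24,   8,   90,  60,  6),
    b_age = c(-0.03, -0.008, -0.08, -0.04, -0.04, 0.5, 1.2, -0.12, -0.06,
              -0.2, -0.4, -0.03),
    b_edu = c(0.15, 0.02, 0.2, 0.1, 0.1, -0.8, -1.5, 0.3, 0.12, 0.2, 1.0, 0.08),
    sigma = c(1.5, 0.5, 2.5, 1.4, 1.4, 10, 25, 4, 2, 8, 10, 1.6),
    orientation = c(1, 1, 1, 1, 1, -1, -1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Default residual covariance of the cognitive measures
#'
#' Compound-symmetric correlation (rho = 0.3) scaled by the per-measure
#' residual sds of [cognitive_measure_info()]; cognitive tests are
#' positively correlated because they share method and trait variance.
#'
#' @param rho common residual correlation between measures.
#' @return A 12 x 12 positive-definite covariance matrix.
#' @export
default_score_covariance <- function(rho = 0.3) {
  info <- cognitive_measure_info()
  p <- nrow(info)
  R <- matrix(rho, p, p); diag(R) <- 1
  D <- diag(info$sigma)
  S <- D %*% R %*% D
  dimnames(S) <- list(info$measure, info$measure)
  S
}

# Moments of the noncentral chi distribution (df k, noncentrality theta^2):
# E and sd of sqrt(X), X ~ ncchisq. Used to calibrate group MDCog targets.
ncchi_moments <- function(k, theta) {
  ncp <- theta^2
  m2 <- k + ncp
  s2 <- sqrt(2 * (k + 2 * ncp))
  # integrate where the density lives; the full half-line loses mass at
  # large noncentrality
  lo <- max(0, m2 - 12 * s2)
  hi <- m2 + 12 * s2
  m1 <- integrate(function(x) sqrt(x) * dchisq(x, k, ncp), lo, hi,
                  rel.tol = 1e-9)$value
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve for (scale c, shift magnitude delta) such that c * chi_k(delta/c)
# matches the target mean exactly and the target sd as closely as the
# isotropic noncentral-chi family allows (its mean/sd ratio is bounded
# below; below the bound the sd is matched at the boundary theta = 0).
calibrate_mdcog <- function(target_mean, target_sd, k = 12L) {
  ratio <- target_mean / target_sd
  r0 <- {
    m <- ncchi_moments(k, 0); m[["mean"]] / m[["sd"]]
  }
  theta <- 0
  if (ratio > r0) {
    f <- function(th) {
      m <- ncchi_moments(k, th)
      m[["mean"]] / m[["sd"]] - ratio
    }
    theta <- stats::uniroot(f, c(0, 60), tol = 1e-8)$root
  }
  m <- ncchi_moments(k, theta)
  cc <- target_mean / m[["mean"]]
  c(scale = cc, delta = cc * theta)
}

#' Generate correlated cognitive scores for a cohort
#'
#' Each measure depends linearly on age and education (coefficients from
#' [cognitive_measure_info()]) plus correlated noise. Group-level cognitive
#' deficits are injected in a latent "deficit" space that the Mahalanobis
#' index recovers: subject deficit = `scale_g * z + shift_g`, z standard
#' normal (12-dim). By default the per-group scale and shift magnitude are
#' calibrated from the cohort spec's MDCog mean/sd targets via
#' noncentral-chi moments; passing `effect` instead applies that explicit
#' 12-vector shift to the MCI-E group only (unit scale everywhere), shifted
#' toward worse performance.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param effect optional numeric length-12 deficit shift for the MCI-E
#'   group (deficit-space units; positive = worse).
#' @param sigma residual covariance (12 x 12, positive definite).
#' @param mdcog_targets list with `mean` and `sd` named per group
#'   (`YA`, `HE`, `MCIE`), used when `effect` is NULL.
#' @param seed integer seed.
#' @return A data frame of class `cognitive_scores`: id, age, education and
#'   the 12 raw measures. The latent per-subject deficit vectors are kept
#'   in `attr(, "deficit")` for generator self-checks.
#' @export
generate_cognitive_scores <- function(cohort, effect = NULL,
                                      sigma = default_score_covariance(),
                                      mdcog_targets = list(
                                        mean = c(YA = 2.91, HE = 3.81, MCIE = 9.30),
                                        sd = c(YA = 0.97, HE = 1.08, MCIE = 1.65)),
                                      seed = 1L) {
  info <- cognitive_measure_info()
  p <- nrow(info)
  if (!is.null(effect) && length(effect) != p)
    stop_gaitssc("'effect' must have length %d", p)
  if (!isTRUE(all.equal(sigma, t(sigma))) ||
      inherits(try(chol(sigma), silent = TRUE), "try-error"))
    stop_gaitssc("'sigma' must be a symmetric positive-definite %dx%d matrix", p, p)
  n <- nrow(cohort)
  set.seed(seed)

  # correlation structure of the deficit space: sigma = A A', deficits d = A u
  A <- t(chol(sigma))

  grp_key <- c("YA" = "YA", "HE" = "HE", "MCI-E" = "MCIE", "normative" = "NORM")
  u <- matrix(rnorm(n * p), n, p)
  shift_d <- matrix(0, n, p) # additive deficit shift on the measure scale
  for (g in unique(as.character(cohort$group))) {
    rows <- which(as.character(cohort$group) == g)
    gk <- if (g %in% names(grp_key)) grp_key[[g]] else "NORM"
    if (!is.null(effect)) {
      if (g == "MCI-E")
        shift_d[rows, ] <- matrix(effect, length(rows), p, byrow = TRUE)
    } else if (gk %in% c("YA", "HE", "MCIE")) {
      cal <- calibrate_mdcog(mdcog_targets$mean[[gk]], mdcog_targets$sd[[gk]], p)
      v <- rep(1 / sqrt(p), p) # deficit direction spread over all measures
      u[rows, ] <- cal[["scale"]] * u[rows, , drop = FALSE] +
        matrix(cal[["delta"]] * v, length(rows), p, byrow = TRUE)
    } # normative subjects: unit scale, zero shift
  }
  deficit <- u %*% t(A) + shift_d # n x p, covariance sigma at unit scale
  colnames(deficit) <- info$measure

  pred <- outer(rep(1, n), info$b0) +
    outer(cohort$age, info$b_age) + outer(cohort$education, info$b_edu)
  raw <- pred - deficit %*% diag(info$orientation)
  colnames(raw) <- info$measure

  out <- data.frame(id = cohort$id, age = cohort$age,
                    education = cohort$education, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(raw))
  attr(out, "deficit") <- deficit
  class(out) <- c("cognitive_scores", class(out))
  out
}

#' Generate a synthetic normative sample
#'
#' Subjects spanning the adult age range with zero group shift and unit
#' deficit scale; used to fit the normative model behind the MDCog index.
#'
#' @param n number of normative subjects.
#' @param age_range,education_range sampling ranges.
#' @param sigma residual covariance passed to [generate_cognitive_scores()].
#' @param seed integer seed.
#' @return A `cognitive_scores` data frame.
#' @export
generate_normative_scores <- function(n = 400L, age_range = c(20, 90),
                                      education_range = c(6L, 20L),
                                      sigma = default_score_covariance(),
                                      seed = 1L) {
  set.seed(seed)
  cohort <- data.frame(
    id = sprintf("N%04d", seq_len(n)),
    group = "normative",
    age = runif(n, age_range[1], age_range[2]),
    education = sample(seq(education_range[1], education_range[2]), n, TRUE),
    stringsAsFactors = FALSE)
  generate_cognitive_scores(cohort, sigma = sigma, seed = seed + 1L)
}
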