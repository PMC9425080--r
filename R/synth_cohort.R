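#' Specification of a synthetic study cohort
#'
#' Encodes the demographic structure of the cohort the generators emulate:
#' three groups — young adults (YA), healthy elderly (HE) and cognitively
#' impaired elderly (MCI-E) — with group sizes, age ranges, anthropometry
#' and target distributions of the MDCog summary cognitive index. Defaults
#' reproduce the reference cohort: 40 / 62 / 23 subjects and MDCog
#' 2.91 +/- 0.97, 3.81 +/- 1.08, 9.30 +/- 1.65.
#'
#' @param n_ya,n_he,n_mcie non-negative group sizes.
#' @param age_mean,age_sd,age_range per-group age distributions (years);
#'   ages are drawn from a normal truncated to the range.
#' @param mdcog_mean,mdcog_sd per-group targets for the MDCog index.
#' @param height_mean,height_sd,weight_mean,weight_sd anthropometry (cm, kg).
#' @param female_prop per-group proportion of women.
#' @param education_range years of schooling, drawn uniformly and
#'   independently of group.
#' @param seed integer seed used by [generate_cohort()].
#' @return An object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_ya = 40L, n_he = 62L, n_mcie = 23L,
                        age_mean = c(YA = 27.65, HE = 72.23, MCIE = 76.00),
                        age_sd = c(YA = 4.14, HE = 6.59, MCIE = 7.43),
                        age_range = list(YA = c(22, 38), HE = c(60, 88),
                                         MCIE = c(61, 87)),
                        mdcog_mean = c(YA = 2.91, HE = 3.81, MCIE = 9.30),
                        mdcog_sd = c(YA = 0.97, HE = 1.08, MCIE = 1.65),
                        height_mean = c(YA = 167.97, HE = 161.57, MCIE = 159.69),
                        height_sd = c(YA = 8.19, HE = 9.92, MCIE = 8.95),
                        weight_mean = c(YA = 70.20, HE = 68.47, MCIE = 64.13),
                        weight_sd = c(YA = 14.69, HE = 16.59, MCIE = 14.63),
                        female_prop = c(YA = 0.50, HE = 0.597, MCIE = 0.695),
                        education_range = c(6L, 20L),
                        seed = 1L) {
  counts <- c(n_ya, n_he, n_mcie)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_gaitssc("group counts must be non-negative")
  if (any(unlist(mdcog_sd) < 0) || any(unlist(age_sd) < 0))
    stop_gaitssc("standard deviations must be non-negative")
  for (g in names(age_range))
    if (diff(age_range[[g]]) <= 0) stop_gaitssc("empty age range for group %s", g)
  spec <- list(n_ya = as.integer(n_ya), n_he = as.integer(n_he),
               n_mcie = as.integer(n_mcie),
               age_mean = age_mean, age_sd = age_sd, age_range = age_range,
               mdcog_mean = mdcog_mean, mdcog_sd = mdcog_sd,
               height_mean = height_mean, height_sd = height_sd,
               weight_mean = weight_mean, weight_sd = weight_sd,
               female_prop = female_prop, education_range = education_range,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

rnorm_trunc <- function(n, mean, sd, range) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort
#'
#' Draws subject records (id, group, age, sex, height, weight, education)
#' according to a [cohort_spec()]. Deterministic for a fixed spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with one row per subject; `group` is a factor with
#'   levels `YA`, `HE`, `MCI-E`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  key <- c(YA = "YA", HE = "HE", MCIE = "MCI-E")
  rows <- lapply(names(key), function(g) {
    n <- switch(g, YA = spec$n_ya, HE = spec$n_he, MCIE = spec$n_mcie)
    if (n == 0L) return(NULL)
    data.frame(
      group = key[[g]],
      age = rnorm_trunc(n, spec$age_mean[[g]], spec$age_sd[[g]], spec$age_range[[g]]),
      sex = ifelse(runif(n) < spec$female_prop[[g]], "F", "M"),
      height = rnorm(n, spec$height_mean[[g]], spec$height_sd[[g]]),
      weight = rnorm(n, spec$weight_mean[[g]], spec$weight_sd[[g]]),
      education = sample(seq(spec$education_range[1], spec$education_range[2]),
                         n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), age = numeric(0), sex = character(0),
                      height = numeric(0), weight = numeric(0),
                      education = integer(0), stringsAsFactors = FALSE)
  out$id <- sprintf("S%03d", seq_len(nrow(out)))
  out$group <- factor(out$group, levels = c("YA", "HE", "MCI-E"))
  out[, c("id", "group", "age", "sex", "height", "weight", "education")]
}
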