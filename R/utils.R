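#' Derive a stage seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each named
#' stage gets its own reproducible sub-seed so stages can be rerun in
#' isolation. The derivation hashes the stage name onto the root with a
#' fixed multiplier modulo a Mersenne prime, so it is stable across
#' platforms and R versions.
#'
#' @param root integer root seed.
#' @param stage character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(root) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_gaitssc <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_gaitssc("'%s' must be a single finite number in [%g, %g]", name, lower, upper)
  x
}

# sample standard deviation / mean, as a percentage
cov_percent <- function(x) {
  if (length(x) < 3L) stop_gaitssc("coefficient of variation needs at least 3 values")
  100 * stats::sd(x) / mean(x)
}

# Stratified subsample of indices: draws round(fraction * n_g) from every
# stratum (at least 1), preserving class presence.
stratified_sample <- function(labels, fraction) {
  idx <- integer(0)
  for (lv in unique(labels)) {
    g <- which(labels == lv)
    k <- max(1L, round(fraction * length(g)))
    idx <- c(idx, if (length(g) == 1L) g else sample(g, k))
  }
  sort(idx)
}

# Stratified k-fold assignment; every fold holds both classes when feasible.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    g <- which(labels == lv)
    if (length(g) < k && length(g) < 2L)
      stop_gaitssc("class '%s' too small for %d-fold stratification", lv, k)
    fold[g] <- sample(rep_len(seq_len(k), length(g)))
  }
  fold
}

# Mann-Whitney AUC of scores for a binary outcome (1 = positive class).
auc_rank <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
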