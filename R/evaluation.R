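# Two-way (GROUP x TASK) sums of squares from a subjects x tasks value
# matrix with proportional cell sizes (every subject performs every task).
# Returns the three F statistics; undefined ratios (zero error mean square)
# are mapped to 0 when the effect is also null, Inf otherwise.
anova2_F <- function(V, gid, a) {
  n <- nrow(V); t <- ncol(V); N <- n * t
  ng <- tabulate(gid, a)
  gm <- sum(V) / N
  ss_tot <- sum(V^2) - N * gm^2
  sub_tot <- rowSums(V)
  Tg <- rowsum(sub_tot, gid)[, 1]
  ss_a <- sum(Tg^2 / (ng * t)) - N * gm^2
  Tt <- colSums(V)
  ss_b <- sum(Tt^2) / n - N * gm^2
  C <- rowsum(V, gid) # a x t cell sums
  ss_cells <- sum(C^2 / ng) - N * gm^2
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- ss_tot - ss_cells
  df <- c(a - 1, t - 1, (a - 1) * (t - 1), N - a * t)
  ms_err <- ss_err / df[4]
  fr <- function(ss, d) {
    if (ms_err <= 1e-12) { if (ss / d <= 1e-12) 0 else Inf } else (ss / d) / ms_err
  }
  c(group = fr(max(ss_a, 0), df[1]), task = fr(max(ss_b, 0), df[2]),
    interaction = fr(max(ss_ab, 0), df[3]))
}

#' Permutation two-way ANOVA on a gait feature
#'
#' Non-parametric two-way analysis of variance with GROUP (between
#' subjects) and TASK (within subjects) as main effects plus their
#' interaction. Classical F statistics are computed on the observed data;
#' their null distributions come from restricted permutations — group
#' labels permuted across subjects for the GROUP and interaction effects,
#' task labels permuted within each subject for the TASK effect — with
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param values numeric subjects x tasks matrix of one feature (each
#'   subject must have every task; no missing values).
#' @param groups group label per subject (row).
#' @param n_perm number of permutations (>= 99; 999 by default).
#' @param seed integer seed.
#' @return A list of class `anova2_result`: `F` (observed statistics),
#'   `p` (permutation p-values), `n_perm`.
#' @export
permutation_anova2 <- function(values, groups, n_perm = 999L, seed = 1L) {
  V <- as.matrix(values)
  if (anyNA(V)) stop_gaitssc("missing cells: every subject needs every task")
  n <- nrow(V); t <- ncol(V)
  g <- factor(groups)
  if (length(g) != n) stop_gaitssc("groups must match the rows of values")
  a <- nlevels(g)
  if (a < 2L || t < 2L) stop_gaitssc("need at least 2 groups and 2 tasks")
  if (n_perm < 99L) stop_gaitssc("n_perm must be at least 99")
  gid <- as.integer(g)
  set.seed(seed)

  obs <- anova2_F(V, gid, a)

  ng <- tabulate(gid, a); N <- n * t
  df <- c(a - 1, t - 1, (a - 1) * (t - 1), N - a * t)
  block <- rep(seq_len(n_perm), each = n)
  key <- (block - 1L) * a + rep(gid, times = n_perm)

  # F statistics of all row permutations of a subjects x tasks matrix,
  # vectorized via one rowsum over (permutation x group) cells
  perm_F <- function(M) {
    gmM <- sum(M) / N
    ss_totM <- sum(M^2) - N * gmM^2
    ss_bM <- sum(colSums(M)^2) / n - N * gmM^2
    P <- vapply(seq_len(n_perm), function(j) sample.int(n), integer(n))
    MP <- M[as.vector(P), , drop = FALSE]
    Tg_all <- rowsum(rowSums(MP), key)[, 1] # (n_perm*a), ordered by block
    ss_a_all <- colSums(matrix(Tg_all^2 / rep(ng * t, n_perm), a, n_perm)) -
      N * gmM^2
    Csum <- rowsum(MP, key) # (n_perm*a) x t
    ss_cells_all <- colSums(matrix(rowSums(Csum^2 / rep(ng, n_perm)),
                                   a, n_perm)) - N * gmM^2
    ss_ab_all <- ss_cells_all - ss_a_all - ss_bM
    ms_err_all <- (ss_totM - ss_cells_all) / df[4]
    list(Fg = (pmax(ss_a_all, 0) / df[1]) / ms_err_all,
         Fab = (pmax(ss_ab_all, 0) / df[3]) / ms_err_all)
  }

  # GROUP null: permute whole subjects on the raw data
  Fg <- perm_F(V)$Fg
  # interaction null: permute subjects on the residuals after both main
  # effects, so large main effects cannot masquerade as interaction
  R <- V - rowMeans(rowsum(V, gid) / ng)[gid] -
    matrix(colMeans(V), n, t, byrow = TRUE) + mean(V)
  Fab <- perm_F(R)$Fab

  gm <- sum(V) / N
  ss_tot <- sum(V^2) - N * gm^2

  # TASK null: permute task labels within each subject
  tp <- perms_of(t)
  idx <- sample.int(nrow(tp), n * n_perm, replace = TRUE)
  cols <- tp[idx, , drop = FALSE]
  rows_vec <- rep(seq_len(n), n_perm)
  VT <- matrix(V[(cols - 1L) * n + rows_vec], n * n_perm, t)
  Ttask <- rowsum(VT, block) # n_perm x t task totals
  ss_b_all <- rowSums(Ttask^2) / n - N * gm^2
  CsumT <- rowsum(VT, key)
  ss_cells_T <- colSums(matrix(rowSums(CsumT^2 / rep(ng, n_perm)), a, n_perm)) - N * gm^2
  ss_err_T <- ss_tot - ss_cells_T
  Ft <- (pmax(ss_b_all, 0) / df[2]) / (ss_err_T / df[4])

  pval <- function(f_obs, f_perm) {
    if (!is.finite(f_obs) || f_obs <= 0) return(1)
    (1 + sum(f_perm >= f_obs, na.rm = TRUE)) / (1 + n_perm)
  }
  structure(list(F = obs,
                 p = c(group = pval(obs["group"], Fg),
                       task = pval(obs["task"], Ft),
                       interaction = pval(obs["interaction"], Fab)),
                 n_perm = n_perm),
            class = "anova2_result")
}

# All permutations of 1..k (k small).
perms_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- perms_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Rank-based comparison of model AUC distributions
#'
#' Pools the AUC samples of all models, ranks them jointly, and compares
#' each model's mean rank with a reference model's: the difference is
#' tested with the normal approximation of the rank-sum statistic and
#' Bonferroni-corrected over the number of comparisons; simultaneous
#' confidence intervals for the mean ranks use the corrected level.
#' Rank-based, so invariant to any common monotone transform of the AUCs.
#'
#' @param auc_samples named list of equal-length numeric AUC vectors.
#' @param reference name of the reference model.
#' @param alpha family-wise significance level.
#' @return A data frame (class `model_comparison`): model, n, mean_rank,
#'   ci_lo, ci_hi, est (mean-rank difference vs the reference), p, p_adj,
#'   significant.
#' @export
compare_model_aucs <- function(auc_samples, reference = names(auc_samples)[1],
                               alpha = 0.05) {
  m <- length(auc_samples)
  if (m < 2L) stop_gaitssc("need at least 2 models to compare")
  if (!reference %in% names(auc_samples))
    stop_gaitssc("unknown reference model '%s'", reference)
  lens <- lengths(auc_samples)
  if (length(unique(lens)) != 1L)
    stop_gaitssc("AUC samples must have equal length")
  pooled <- unlist(auc_samples, use.names = FALSE)
  rk <- rank(pooled)
  model <- rep(names(auc_samples), lens)
  N <- length(pooled)
  mean_rank <- tapply(rk, model, mean)[names(auc_samples)]
  n_comp <- m - 1L
  zcrit <- qnorm(1 - alpha / (2 * n_comp))
  se_i <- sqrt(N * (N + 1) / 12 / lens)
  se_diff <- sqrt(N * (N + 1) / 12 * (1 / lens + 1 / lens[[reference]]))
  est <- mean_rank - mean_rank[[reference]]
  p <- 2 * pnorm(-abs(est) / se_diff)
  p[names(p) == reference] <- NA
  p_adj <- pmin(1, p * n_comp)
  out <- data.frame(model = names(auc_samples), n = as.integer(lens),
                    mean_rank = as.numeric(mean_rank),
                    ci_lo = as.numeric(mean_rank - zcrit * se_i),
                    ci_hi = as.numeric(mean_rank + zcrit * se_i),
                    est = as.numeric(est), p = as.numeric(p),
                    p_adj = as.numeric(p_adj),
                    significant = !is.na(p_adj) & p_adj < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("model_comparison", "data.frame")
  out
}

# Shrinkage linear discriminant analysis: pooled within-class covariance
# shrunk toward its diagonal with the analytic intensity, discriminant
# direction w = S^-1 (mu_pos - mu_neg), score = x'w (higher = positive).
rlda_fit <- function(X, y01) {
  mu0 <- colMeans(X[y01 == 0, , drop = FALSE])
  mu1 <- colMeans(X[y01 == 1, , drop = FALSE])
  R <- rbind(sweep(X[y01 == 0, , drop = FALSE], 2, mu0),
             sweep(X[y01 == 1, , drop = FALSE], 2, mu1))
  S <- crossprod(R) / (nrow(R) - 2)
  lam <- shrinkage_intensity(R)
  S <- (1 - lam) * S + lam * diag(diag(S), ncol(X))
  diag(S) <- diag(S) + 1e-8 * mean(diag(S)) # guards exact singularity
  list(w = solve(S, mu1 - mu0), mu0 = mu0, mu1 = mu1)
}

rlda_score <- function(fit, X) as.numeric(as.matrix(X) %*% fit$w)

#' Baseline classifiers: SVM and regularized LDA
#'
#' Repeated stratified 10-fold cross-validation of a support vector
#' machine (radial kernel, library defaults) and a shrinkage-regularized
#' linear discriminant analysis, sharing identical fold assignments so the
#' comparison is paired. Feature standardization is fitted inside each
#' training fold (the SVM scales internally from its training data). One
#' AUC is computed per repetition from the pooled held-out scores; SVM
#' score orientation is fixed on the training fold only.
#'
#' @param X feature matrix.
#' @param y two-class labels.
#' @param folds folds per repetition.
#' @param reps repetitions.
#' @param positive positive-class label.
#' @param seed integer seed.
#' @return A list of class `baseline_result`: per classifier the AUC
#'   vector, mean and sd; plus the fold assignments (reps x n matrix) for
#'   reuse by other protocols.
#' @export
baseline_classifiers <- function(X, y, folds = 10L, reps = 500L,
                                 positive = NULL, seed = 1L) {
  X <- as.matrix(X)
  lab <- label01(y, positive)
  if (min(table(lab$y)) < folds)
    stop_gaitssc("smallest class (%d) is too small for %d stratified folds",
                 min(table(lab$y)), folds)
  set.seed(seed)
  n <- nrow(X)
  fold_mat <- matrix(0L, reps, n)
  auc_svm <- auc_lda <- numeric(reps)
  yf <- factor(lab$y, levels = c(0, 1))
  for (r in seq_len(reps)) {
    fold <- stratified_folds(lab$y, folds)
    fold_mat[r, ] <- fold
    sc_svm <- sc_lda <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        scale = TRUE)
      dv_tr <- attr(predict(fit, X[tr, , drop = FALSE],
                            decision.values = TRUE), "decision.values")[, 1]
      flip <- if (auc_rank(dv_tr, lab$y[tr] == 1) < 0.5) -1 else 1
      dv <- attr(predict(fit, X[!tr, , drop = FALSE],
                         decision.values = TRUE), "decision.values")[, 1]
      sc_svm[!tr] <- flip * dv

      z <- zscore_by(X[tr, , drop = FALSE])
      lda <- rlda_fit(z$X, lab$y[tr])
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, z$mu), 2, z$sd, "/")
      sc_lda[!tr] <- rlda_score(lda, Xte)
    }
    auc_svm[r] <- auc_rank(sc_svm, lab$y == 1)
    auc_lda[r] <- auc_rank(sc_lda, lab$y == 1)
  }
  structure(list(
    svm = list(auc = auc_svm, mean = mean(auc_svm), sd = sd(auc_svm)),
    lda = list(auc = auc_lda, mean = mean(auc_lda), sd = sd(auc_lda)),
    folds = fold_mat, positive = lab$positive, seed = seed),
    class = "baseline_result")
}
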