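# Code two-class labels as 0/1 with an explicit positive class.
label01 <- function(y, positive = NULL) {
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) != 2L) stop_gaitssc("need exactly two classes, got %d", length(cls))
  positive <- positive %||% (if ("MCI-E" %in% cls) "MCI-E" else cls[2])
  if (!positive %in% cls) stop_gaitssc("positive class '%s' not present", positive)
  list(y = as.numeric(y == positive), positive = positive)
}

# z-score columns with the statistics of a reference subset; zero-variance
# columns are centered only (coefficient stays 0 downstream).
zscore_by <- function(X, ref_rows = seq_len(nrow(X))) {
  mu <- colMeans(X[ref_rows, , drop = FALSE])
  sdv <- apply(X[ref_rows, , drop = FALSE], 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
}

#' Stability selection with resampled elastic-net fits
#'
#' The biomarker-selection step of the Stable Sparse Classifiers
#' procedure. In each of `n_iter` iterations a stratified `subject_fraction`
#' of the subjects and a random `feature_fraction` of the features are
#' drawn; a univariate screening step removes features with minimal
#' contribution; the elastic net is fitted at a cross-validated lambda; a
#' feature counts as selected when its coefficient is non-zero. The
#' selection frequency of a feature is its selections divided by the
#' number of iterations in which it was offered to the model (survived
#' feature subsampling and screening); features with frequency strictly
#' above `threshold` form the stable set.
#'
#' @param X n x p numeric feature matrix (or data frame of features only).
#' @param y two-class labels.
#' @param n_iter resampling iterations.
#' @param subject_fraction,feature_fraction resampled fractions.
#' @param threshold consistency threshold on the selection frequency.
#' @param keep_fraction screening retention fraction.
#' @param config an [enet_config()].
#' @param positive positive-class label (defaults to `MCI-E` when present).
#' @param seed integer seed; the whole procedure is replayable from it.
#' @return A list of class `stability_result`: `frequency` (named,
#'   in `[0,1]`), `stable` (character vector of stable features),
#'   `selected`/`offered` counts, and the procedure parameters.
#' @export
stability_selection <- function(X, y, n_iter = 500L, subject_fraction = 0.7,
                                feature_fraction = 0.7, threshold = 0.5,
                                keep_fraction = 0.5, config = enet_config(),
                                positive = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop_gaitssc("need at least 2 features")
  lab <- label01(y, positive)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  p <- ncol(X)
  selected <- offered <- setNames(numeric(p), colnames(X))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    rows <- stratified_sample(lab$y, subject_fraction)
    feats <- sort(sample.int(p, max(2L, round(feature_fraction * p))))
    Xs <- X[rows, feats, drop = FALSE]
    ys <- lab$y[rows]
    if (length(unique(ys)) < 2L) next # cannot happen with stratified draws
    if (config$standardize) Xs <- zscore_by(Xs)$X
    kept <- screen_features(Xs, ys, keep_fraction)
    offered[feats[kept]] <- offered[feats[kept]] + 1
    Xk <- Xs[, kept, drop = FALSE]
    cv <- cv_select_lambda(Xk, ys, config)
    fit <- elastic_net_fit(Xk, ys, cv$lambda, config)
    nz <- kept[fit$coefficients != 0]
    selected[feats[nz]] <- selected[feats[nz]] + 1
  }
  frequency <- ifelse(offered > 0, selected / offered, 0)
  structure(list(frequency = frequency,
                 stable = names(frequency)[frequency > threshold],
                 selected = selected, offered = offered,
                 n_iter = n_iter, subject_fraction = subject_fraction,
                 feature_fraction = feature_fraction, threshold = threshold,
                 keep_fraction = keep_fraction, positive = lab$positive,
                 seed = seed),
            class = "stability_result")
}

#' Resampled ROC/AUC validation of a stable feature set
#'
#' The validation step of the Stable Sparse Classifiers procedure: in each
#' iteration a stratified `train_fraction` of the subjects trains an
#' elastic net (cross-validated lambda) on the stable features and the
#' remaining subjects are scored with `phi0 + x' phi`; the ROC/AUC of the
#' held-out scores is recorded. Reports the AUC distribution (its median
#' is the procedure's accuracy measure), pointwise 95% ROC bands, and the
#' pooled held-out scores used for operating-point selection.
#'
#' @param X feature matrix already restricted to the stable set.
#' @param y two-class labels.
#' @param n_iter iterations.
#' @param train_fraction stratified training fraction.
#' @param config an [enet_config()].
#' @param positive positive-class label.
#' @param seed integer seed.
#' @param fpr_grid grid on which the ROC bands are interpolated.
#' @return A list of class `validation_result`: `auc` (length `n_iter`),
#'   `median_auc`, `roc` (data frame `fpr`, `tpr_lo`, `tpr_med`,
#'   `tpr_hi`), pooled `scores`/`labels`, and metadata. When `X` has no
#'   columns an explicit no-biomarkers result is returned instead of an
#'   error (`no_biomarkers = TRUE`, `median_auc = NA`).
#' @export
validate_model <- function(X, y, n_iter = 500L, train_fraction = 0.7,
                           config = enet_config(), positive = NULL,
                           seed = 1L, fpr_grid = seq(0, 1, by = 0.01)) {
  X <- as.matrix(X)
  lab <- label01(y, positive)
  if (ncol(X) == 0L)
    return(structure(list(no_biomarkers = TRUE, auc = numeric(0),
                          median_auc = NA_real_, roc = NULL,
                          scores = numeric(0), labels = numeric(0),
                          positive = lab$positive),
                     class = "validation_result"))
  set.seed(seed)
  aucs <- numeric(n_iter)
  tpr_mat <- matrix(NA_real_, n_iter, length(fpr_grid))
  pooled_scores <- vector("list", n_iter)
  pooled_labels <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    tr <- stratified_sample(lab$y, train_fraction)
    te <- setdiff(seq_len(nrow(X)), tr)
    if (!length(te) || length(unique(lab$y[te])) < 2L) {
      aucs[it] <- NA_real_; next
    }
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (config$standardize) {
      z <- zscore_by(Xtr)
      Xtr <- z$X
      Xte <- sweep(sweep(Xte, 2, z$mu), 2, z$sd, "/")
    }
    cv <- cv_select_lambda(Xtr, lab$y[tr], config)
    fit <- elastic_net_fit(Xtr, lab$y[tr], cv$lambda, config)
    sc <- fit$intercept + as.numeric(Xte %*% fit$coefficients)
    aucs[it] <- auc_rank(sc, lab$y[te] == 1)
    tpr_mat[it, ] <- roc_tpr_at(sc, lab$y[te] == 1, fpr_grid)
    pooled_scores[[it]] <- sc
    pooled_labels[[it]] <- lab$y[te]
  }
  qs <- apply(tpr_mat, 2, quantile, probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
  structure(list(no_biomarkers = FALSE, auc = aucs,
                 median_auc = median(aucs, na.rm = TRUE),
                 roc = data.frame(fpr = fpr_grid, tpr_lo = qs[1, ],
                                  tpr_med = qs[2, ], tpr_hi = qs[3, ]),
                 scores = unlist(pooled_scores), labels = unlist(pooled_labels),
                 n_iter = n_iter, train_fraction = train_fraction,
                 positive = lab$positive, seed = seed),
            class = "validation_result")
}

# True-positive rate of the score-based classifier at given false-positive
# rates (step-function ROC interpolated on the grid).
roc_tpr_at <- function(scores, positive, fpr_grid) {
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- vapply(thr, function(h) mean(scores[!positive] >= h), 0)
  tpr <- vapply(thr, function(h) mean(scores[positive] >= h), 0)
  vapply(fpr_grid, function(f) max(0, tpr[fpr <= f], na.rm = TRUE), 0)
}

#' Operating point at a target sensitivity
#'
#' Chooses the score threshold whose pooled-iteration sensitivity is the
#' smallest value at or above the target (detecting at least that fraction
#' of the impaired class) and reports the resulting specificity and the
#' accuracy implied by the pooled class prevalences. When the only
#' qualifying threshold labels every subject positive, the point is
#' flagged as degenerate.
#'
#' @param vr a [validate_model()] result.
#' @param target_sensitivity required minimum sensitivity.
#' @return A list: `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `target_attained`.
#' @export
operating_point <- function(vr, target_sensitivity = 0.90) {
  stopifnot(inherits(vr, "validation_result"))
  if (isTRUE(vr$no_biomarkers) || !length(vr$scores))
    stop_gaitssc("no validation scores available (empty stable set?)")
  pos <- vr$labels == 1
  thr <- c(sort(unique(vr$scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(h) mean(vr$scores[pos] >= h), 0)
  spec <- vapply(thr, function(h) mean(vr$scores[!pos] < h), 0)
  ok <- which(sens >= target_sensitivity)
  i <- ok[which.min(sens[ok])]
  acc <- sens[i] * mean(pos) + spec[i] * mean(!pos)
  list(threshold = thr[i], sensitivity = sens[i], specificity = spec[i],
       accuracy = acc, target_attained = spec[i] > 0 || sens[i] < 1)
}
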