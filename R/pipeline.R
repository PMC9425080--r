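#' Default pipeline configuration
#'
#' All stage parameters in one place, each defaulting to the protocol
#' value where one exists: 100 Hz sampling, 3 Hz 4th-order zero-lag
#' low-pass, 3 s segment trimming, auto wavelet scale, NormalW as the
#' dual-task-cost reference, 1,000 k-means restarts, SSC with 500
#' iterations at 70% subjects / 70% features and a 50% consistency
#' threshold, 500 validation iterations at a 70/30 split, 90% target
#' sensitivity, 10-fold x 500-repetition baselines, 999 ANOVA
#' permutations.
#'
#' @param ... overrides of any default (unknown names are rejected).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    sampling_rate = 100, filter_cutoff = 3, filter_order = 4,
    trim_seconds = 3, wavelet_scale = NULL, dtc_reference = "NormalW",
    distance = 20,
    normative_n = 400, kmeans_repeats = 1000L, age_threshold = 60,
    n_iter_stability = 500L, n_iter_validation = 500L,
    subject_fraction = 0.7, feature_fraction = 0.7,
    stability_threshold = 0.5, keep_fraction = 0.5,
    gamma = 0.5, nlambda = 100L, n_folds = 10L,
    target_sensitivity = 0.90,
    baseline_folds = 10L, baseline_reps = 500L,
    n_perm_anova = 999L,
    models = names(enumerate_models()),
    comparison = c("HE", "MCI-E"),
    run_baselines = TRUE, run_anova = TRUE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_gaitssc("unknown config fields: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   a `run_config` (round-trips losslessly).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# Run the signal chain for one raw recording: tilt correction, zero-lag
# low-pass, turn split + trimming, event detection and STGF per direction.
# Returns a list of two named 16-vectors, or NULL (with a message) when a
# stage fails for this recording.
process_recording <- function(rec, config, height) {
  res <- try({
    rec2 <- tilt_correct(rec)
    rec2 <- lowpass_recording(rec2, config$filter_cutoff, config$filter_order)
    segs <- split_segments(rec2, trim = config$trim_seconds)
    lapply(segs, function(sg) {
      ev <- detect_gait_events(sg, wavelet_scale = config$wavelet_scale)
      compute_stgf(compute_stride_params(ev), sg, height = height)
    })
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    message(sprintf("subject %s task %s: %s", attr(rec, "subject_id"),
                    attr(rec, "task"), attr(res, "condition")$message))
    return(NULL)
  }
  res
}

# Gait signal stage over a whole cohort: each subject gets a consistent
# individual deviation from the group profile (erratic hard-dual-task
# compliance in the impaired group widens that task's spread), then each
# subject x task recording is simulated, run through the signal chain,
# and assembled into the direction-averaged 96-measure feature table.
simulate_gait_features <- function(cohort, config, seed,
                                   profiles = default_gait_profiles()) {
  sds <- c(mean_step_time = 0.10, step_time_cov = 0.40, accel_rms = 0.22,
           step_length = 0.12, double_support_frac = 0.12)
  stgf <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$id[i]
    grp <- as.character(cohort$group[i])
    set.seed(derive_seed(seed, paste(id, "subject")))
    f_subj <- exp(rnorm(length(sds), 0, sds))
    subj <- list()
    for (tk in task_names()) {
      set.seed(derive_seed(seed, paste(id, tk, "profile")))
      scale <- if (grp == "MCI-E" && tk == "HardD") 3 else 1
      f_task <- exp(rnorm(length(sds), 0, scale * sds / 2))
      prof <- jitter_gait_profile(profiles[[grp]][[tk]], sds,
                                  factors = f_subj * f_task)
      sim <- try(generate_acceleration(
        prof, task = tk, distance = config$distance,
        sampling_rate = config$sampling_rate,
        seed = derive_seed(seed, paste(id, tk)), subject_id = id),
        silent = TRUE)
      if (inherits(sim, "try-error")) { # e.g. walk too fast for the trim
        message(sprintf("subject %s task %s: %s", id, tk,
                        attr(sim, "condition")$message))
        subj[tk] <- list(NULL)
        next
      }
      subj[[tk]] <- process_recording(sim$recording, config, cohort$height[i])
    }
    stgf[[id]] <- subj
  }
  assemble_feature_table(stgf, dtc_reference = config$dtc_reference)
}

# Cognitive stage: synthetic normative sample + study scores, normative
# model fit, MDCog, and k-means/age group labels.
cognitive_stage <- function(cohort, config, seed) {
  normative <- generate_normative_scores(config$normative_n,
                                         seed = derive_seed(seed, "normative"))
  scores <- generate_cognitive_scores(cohort, seed = derive_seed(seed, "scores"))
  model <- fit_normative_model(normative)
  mdcog <- compute_mdcog(scores, model)
  labels <- cluster_groups(mdcog, cohort$age, repeats = config$kmeans_repeats,
                           age_threshold = config$age_threshold,
                           seed = derive_seed(seed, "kmeans"))
  list(scores = scores, normative_model = model, mdcog = mdcog,
       labels = labels)
}

# SSC + baselines for one feature-subset model.
ssc_stage <- function(features, y, model_id, config, seed) {
  cols <- select_model_columns(features, model_id)
  X <- as.matrix(cols[, setdiff(names(cols), c("id", "group", "label")),
                      drop = FALSE])
  ec <- enet_config(gamma = config$gamma, nlambda = config$nlambda,
                    n_folds = config$n_folds)
  stab <- stability_selection(
    X, y, n_iter = config$n_iter_stability,
    subject_fraction = config$subject_fraction,
    feature_fraction = config$feature_fraction,
    threshold = config$stability_threshold,
    keep_fraction = config$keep_fraction, config = ec,
    seed = derive_seed(seed, paste("stab", model_id)))
  val <- validate_model(
    X[, stab$stable, drop = FALSE], y,
    n_iter = config$n_iter_validation,
    train_fraction = config$subject_fraction, config = ec,
    seed = derive_seed(seed, paste("val", model_id)))
  op <- if (!isTRUE(val$no_biomarkers) && length(val$scores))
    operating_point(val, config$target_sensitivity) else NULL
  base <- NULL
  if (isTRUE(config$run_baselines))
    base <- baseline_classifiers(X, y, folds = config$baseline_folds,
                                 reps = config$baseline_reps,
                                 seed = derive_seed(seed, paste("base", model_id)))
  list(model = model_id, stability = stab, validation = val,
       operating_point = op, baselines = base)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode simulates the cohort, cognitive scores and gait signals,
#' then runs every stage end to end: signal conditioning and event
#' detection, feature extraction into the 96-measure table, MDCog and
#' group definition, the Stable Sparse Classifiers procedure per
#' feature-subset model, baseline classifiers, permutation ANOVA per gait
#' feature, and the rank-based model comparison. From-files mode ingests a
#' prepared feature table plus cognitive score tables instead of
#' simulating. All randomness derives from `config$seed`.
#'
#' @param config a [run_config()].
#' @param mode `"synthetic"` or `"from-files"`.
#' @param inputs for from-files mode: list with `features` (path to a
#'   feature-table CSV containing an `id` column), `scores`, `normative`
#'   (cognitive score CSVs) and `cohort` (demographics CSV with id, group,
#'   age, height, education).
#' @param out_dir optional directory for artifacts (CSV/JSON + manifest).
#' @return A list of class `gaitssc_run` with elements `cohort`,
#'   `features`, `cognitive`, `ssc` (per model), `anova`,
#'   `model_comparison`, `config`.
#' @export
run_pipeline <- function(config = run_config(), mode = c("synthetic", "from-files"),
                         inputs = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  seed <- config$seed

  if (mode == "synthetic") {
    cohort <- generate_cohort(cohort_spec(seed = derive_seed(seed, "cohort")))
    cognitive <- cognitive_stage(cohort, config, seed)
    features <- simulate_gait_features(cohort, config, seed)
  } else {
    if (is.null(inputs)) stop_gaitssc("from-files mode needs 'inputs'")
    cohort <- read.csv(inputs$cohort, stringsAsFactors = FALSE)
    cohort$group <- factor(cohort$group, levels = c("YA", "HE", "MCI-E"))
    ft <- read_feature_table(inputs$features)
    rownames(ft) <- ft$id
    features <- ft[, setdiff(names(ft), c("id", "group", "label")), drop = FALSE]
    normative <- read.csv(inputs$normative, check.names = FALSE)
    scores <- read.csv(inputs$scores, check.names = FALSE)
    model <- fit_normative_model(normative)
    mdcog <- compute_mdcog(scores, model)
    labels <- cluster_groups(mdcog, cohort$age, repeats = config$kmeans_repeats,
                             age_threshold = config$age_threshold,
                             seed = derive_seed(seed, "kmeans"))
    cognitive <- list(scores = scores, normative_model = model,
                      mdcog = mdcog, labels = labels)
  }

  # classification uses the clustering-derived labels, as in the protocol
  grp <- cognitive$labels$group
  keep_ids <- intersect(rownames(features), cohort$id)
  grp_by_id <- setNames(as.character(grp), cohort$id)[keep_ids]
  in_cmp <- grp_by_id %in% config$comparison
  Xids <- keep_ids[in_cmp]
  y <- grp_by_id[in_cmp]
  feats_cmp <- features[Xids, , drop = FALSE]

  ssc <- lapply(config$models, function(mid)
    ssc_stage(feats_cmp, y, mid, config, seed))
  names(ssc) <- config$models

  anova <- NULL
  if (isTRUE(config$run_anova)) {
    anova <- lapply(stgf_names(), function(f) {
      V <- as.matrix(features[keep_ids,
                              paste(task_names(), f, sep = "::"), drop = FALSE])
      permutation_anova2(V, grp_by_id, n_perm = config$n_perm_anova,
                         seed = derive_seed(seed, paste("anova", f)))
    })
    names(anova) <- stgf_names()
  }

  comparison <- NULL
  aucs <- lapply(ssc, function(s) s$validation$auc)
  aucs <- aucs[vapply(aucs, length, 0L) > 0]
  if (length(aucs) >= 2L && length(unique(lengths(aucs))) == 1L)
    comparison <- compare_model_aucs(aucs, reference = "NormalW")

  run <- structure(list(cohort = cohort, features = features,
                        cognitive = cognitive, ssc = ssc, anova = anova,
                        model_comparison = comparison, config = config),
                   class = "gaitssc_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

# Persist the run: feature table, MDCog/groups, per-model JSON summaries,
# ANOVA table and a manifest with the seed and parameters.
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(run$features, file.path(out_dir, "features.csv"))
  write.csv(data.frame(id = run$cohort$id, group_true = run$cohort$group,
                       mdcog = run$cognitive$mdcog,
                       group = run$cognitive$labels$group),
            file.path(out_dir, "groups.csv"), row.names = FALSE)
  summary_df <- report(run)
  write.csv(summary_df, file.path(out_dir, "model_summary.csv"), row.names = FALSE)
  if (!is.null(run$anova)) {
    an <- do.call(rbind, lapply(names(run$anova), function(f)
      data.frame(feature = f, t(run$anova[[f]]$F), t(run$anova[[f]]$p))))
    names(an) <- c("feature", "F_group", "F_task", "F_interaction",
                   "p_group", "p_task", "p_interaction")
    write.csv(an, file.path(out_dir, "anova.csv"), row.names = FALSE)
  }
  if (!is.null(run$model_comparison))
    write.csv(run$model_comparison, file.path(out_dir, "model_comparison.csv"),
              row.names = FALSE)
  stable <- lapply(run$ssc, function(s)
    as.list(sort(s$stability$frequency[s$stability$stable], decreasing = TRUE)))
  jsonlite::write_json(stable, file.path(out_dir, "stable_biomarkers.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = run$config$seed, config = unclass(run$config),
                   n_subjects = nrow(run$cohort),
                   package_version = as.character(utils::packageVersion("gaitssc")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' One row per feature-subset model: median SSC AUC, operating point at
#' the target sensitivity, number and list of stable biomarkers (sorted by
#' selection frequency), and baseline AUCs when run. Models whose stable
#' set is empty are reported as "no stable biomarkers".
#'
#' @param run a [run_pipeline()] result.
#' @return A data frame.
#' @export
report <- function(run) {
  stopifnot(inherits(run, "gaitssc_run"))
  rows <- lapply(run$ssc, function(s) {
    st <- s$stability
    top <- sort(st$frequency[st$stable], decreasing = TRUE)
    data.frame(
      model = s$model,
      n_stable = length(st$stable),
      stable = if (length(top)) paste(names(top), collapse = ";")
               else "no stable biomarkers",
      median_auc = s$validation$median_auc,
      sensitivity = s$operating_point$sensitivity %||% NA_real_,
      specificity = s$operating_point$specificity %||% NA_real_,
      accuracy = s$operating_point$accuracy %||% NA_real_,
      svm_auc = if (!is.null(s$baselines)) s$baselines$svm$mean else NA_real_,
      lda_auc = if (!is.null(s$baselines)) s$baselines$lda$mean else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
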