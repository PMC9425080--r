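#' Per-foot stride, step and support interval series from gait events
#'
#' Interval definitions: step time = consecutive IC differences (assigned
#' to the foot striking at the end of the interval); stride time = same-foot
#' IC differences; stance = IC to same-foot FC; swing = FC to the same
#' foot's next IC; double support = IC to the opposite foot's FC; single
#' support = the complement of double support within the step.
#'
#' @param events a [gait_events()] object with >= 4 ICs.
#' @return A list of numeric interval series: `step_times` (with
#'   `step_foot` labels), `stride_f1`, `stride_f2`, `stance_f1`,
#'   `stance_f2`, `swing_f1`, `swing_f2`, `double_support`,
#'   `single_support`.
#' @export
compute_stride_params <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  ic <- events$ic_times; fc <- events$fc_times; foot <- events$ic_foot
  n <- length(ic)
  if (n < 4L) stop_gaitssc("need at least 4 initial contacts")

  step_times <- diff(ic)
  step_foot <- foot[-1]
  ds <- fc - ic[-n]            # IC_k -> FC (opposite foot), k = 1..n-1
  ss <- ic[-1] - fc            # FC -> next IC: single support
  # stance of IC_k's foot ends at fc[k+1] (its own toe-off); the foot that
  # toe-offs at fc[k] swings until it strikes again at ic[k+1]
  k <- seq_len(n - 2L)
  stance <- fc[k + 1L] - ic[k]
  stance_foot <- foot[k]
  swing <- ic[-1] - fc
  swing_foot <- events$fc_foot

  per_foot <- function(x, f, lab) x[f == lab]
  stride_foot <- function(lab) diff(ic[foot == lab])
  list(ic_times = ic, step_times = step_times, step_foot = step_foot,
       stride_f1 = stride_foot("F1"), stride_f2 = stride_foot("F2"),
       stance_f1 = per_foot(stance, stance_foot, "F1"),
       stance_f2 = per_foot(stance, stance_foot, "F2"),
       swing_f1 = per_foot(swing, swing_foot, "F1"),
       swing_f2 = per_foot(swing, swing_foot, "F2"),
       double_support = ds, single_support = ss)
}

# Inverted-pendulum step lengths: double integration of the vertical
# acceleration (g -> m/s^2), per-step linear detrend of the displacement,
# amplitude h, step length 2 * sqrt(2 l h - h^2) with l = 0.53 * height.
pendulum_step_lengths <- function(vt, fs, t, ic_times, height_cm) {
  l <- 0.53 * height_cm / 100
  vel <- pracma::cumtrapz(vt * 9.80665)[, 1] / fs
  pos <- pracma::cumtrapz(vel - mean(vel))[, 1] / fs
  sapply(seq_len(length(ic_times) - 1L), function(k) {
    i <- which(t >= ic_times[k] & t < ic_times[k + 1L])
    if (length(i) < 3L) return(NA_real_)
    p <- pos[i]
    p <- p - (p[1] + (seq_along(p) - 1) / (length(p) - 1) * (p[length(p)] - p[1]))
    h <- min(max(p) - min(p), l) # pendulum geometry caps the excursion
    2 * sqrt(pmax(2 * l * h - h^2, 0))
  })
}

#' Compute the sixteen spatio-temporal gait features
#'
#' Duration features are means of the interval series from
#' [compute_stride_params()]; variabilities are coefficients of variation
#' (100 x sample sd / mean); cadence is 60 / mean step time; RMS is the
#' root mean square of the (gravity-free, filtered) vertical acceleration
#' over the segment; step length comes from the inverted-pendulum model
#' with pendulum length 0.53 x body height; gait speed = step length /
#' step time.
#'
#' @param intervals output of [compute_stride_params()].
#' @param vertical_signal gravity-free vertical acceleration (g) aligned to
#'   the events, or an [acceleration_recording()].
#' @param sampling_rate,t0 sampling rate (Hz) and first-sample time (s);
#'   taken from the recording when one is given.
#' @param height body height (cm) for the inverted-pendulum step length.
#' @param distance_walked optional walked distance (m); used for step
#'   length (distance / number of steps) only when `height` is missing.
#' @return Named numeric vector of length 16 (see [stgf_names()]).
#' @export
compute_stgf <- function(intervals, vertical_signal, sampling_rate = NULL,
                         t0 = NULL, height = NULL, distance_walked = NULL) {
  if (inherits(vertical_signal, "accel_recording")) {
    sampling_rate <- sampling_rate %||% sampling_rate(vertical_signal)
    t0 <- t0 %||% vertical_signal$t[1]
    vertical_signal <- vertical_signal$vt
  }
  if (is.null(sampling_rate)) stop_gaitssc("sampling_rate is required")
  t0 <- t0 %||% 0
  st <- intervals$step_times
  if (length(st) < 3L)
    stop_gaitssc("fewer than 3 steps: variability is undefined")

  tvec <- t0 + (seq_along(vertical_signal) - 1) / sampling_rate
  strides <- c(intervals$stride_f1, intervals$stride_f2)
  stpt <- mean(st)

  if (!is.null(height)) {
    ic <- intervals$ic_times %||% (t0 + cumsum(c(0, st)))
    steplg <- mean(pendulum_step_lengths(vertical_signal, sampling_rate, tvec,
                                         ic, height), na.rm = TRUE)
  } else if (!is.null(distance_walked)) {
    steplg <- distance_walked / length(st)
  } else {
    steplg <- NA_real_
  }

  out <- c(
    StpT = stpt,
    StpTCoV = cov_percent(st),
    StrT = mean(strides),
    StrTCoV = cov_percent(strides),
    Cd = 60 / stpt,
    RMS = sqrt(mean(vertical_signal^2)),
    DSD = mean(intervals$double_support),
    SSD = mean(intervals$single_support),
    SwDurF1 = mean(intervals$swing_f1),
    SwDurF2 = mean(intervals$swing_f2),
    StDurF1 = mean(intervals$stance_f1),
    StDurF2 = mean(intervals$stance_f2),
    StepDurF1 = mean(intervals$step_times[intervals$step_foot == "F1"]),
    StepDurF2 = mean(intervals$step_times[intervals$step_foot == "F2"]),
    StepLg = steplg,
    GS = steplg / stpt)
  out[.stgf_names]
}

#' Dual-task cost of a gait feature
#'
#' `DTC = ((single - dual) / single) * 100` (percent, signed): the relative
#' change of a feature between single-task walking (the reference, normal
#' pace) and walking under a concurrent cognitive task.
#'
#' @param single_task_value,dual_task_value feature values (vectorized;
#'   names are preserved).
#' @return Dual-task cost in percent.
#' @export
compute_dtc <- function(single_task_value, dual_task_value) {
  if (any(single_task_value == 0))
    stop_gaitssc("dual-task cost undefined: single-task value is zero")
  (single_task_value - dual_task_value) / single_task_value * 100
}

#' Assemble the per-subject 96-measure feature table
#'
#' For each walking direction, the 16 STGF of the four tasks (64 columns)
#' are augmented with the 16 dual-task costs of each of the two dual tasks
#' against the normal walk of the same direction (32 columns); the two
#' directions are then averaged element-wise, since they are highly
#' correlated. Subjects missing a required task/direction are dropped with
#' a recorded reason.
#'
#' @param stgf nested list: `stgf[[subject]][[task]]` is a list of two
#'   named 16-vectors (one per walking direction).
#' @param tasks tasks to require and include (default all four).
#' @param dtc_reference the single-task reference for dual-task costs.
#' @return A data frame (rownames = subject ids) with `length(tasks) * 16`
#'   STGF columns plus 16 per included dual task; dropped subjects are
#'   listed in `attr(,"dropped")`.
#' @export
assemble_feature_table <- function(stgf, tasks = task_names(),
                                   dtc_reference = "NormalW") {
  duals <- intersect(.dual_tasks, tasks)
  if (length(duals) && !dtc_reference %in% tasks)
    stop_gaitssc("dual-task costs need the reference task '%s'", dtc_reference)
  rows <- list(); dropped <- character(0)
  for (id in names(stgf)) {
    subj <- stgf[[id]]
    ok <- all(vapply(tasks, function(tk)
      !is.null(subj[[tk]]) && length(subj[[tk]]) == 2L &&
        all(vapply(subj[[tk]], function(v) all(is.finite(v[.stgf_names])), TRUE)),
      TRUE))
    if (!ok) {
      dropped <- c(dropped, sprintf("%s: missing or incomplete task data", id))
      next
    }
    per_dir <- lapply(1:2, function(d) {
      vals <- unlist(lapply(tasks, function(tk) {
        v <- subj[[tk]][[d]][.stgf_names]
        names(v) <- paste(tk, .stgf_names, sep = "::")
        v
      }))
      dtcs <- unlist(lapply(duals, function(tk) {
        v <- compute_dtc(subj[[dtc_reference]][[d]][.stgf_names],
                         subj[[tk]][[d]][.stgf_names])
        names(v) <- paste("dtc", tk, .stgf_names, sep = "::")
        v
      }))
      c(vals, dtcs)
    })
    rows[[id]] <- (per_dir[[1]] + per_dir[[2]]) / 2
  }
  if (!length(rows))
    stop_gaitssc("no subject had complete data for the requested tasks")
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Enumerate the eleven feature-subset models
#'
#' The four single walking tasks, the six unordered task pairs, and the
#' all-tasks model.
#'
#' @return Named list mapping model id to its character vector of tasks.
#' @export
enumerate_models <- function() {
  singles <- as.list(.task_names)
  names(singles) <- .task_names
  prs <- utils::combn(.task_names, 2, simplify = FALSE)
  names(prs) <- vapply(prs, paste, "", collapse = "+")
  c(singles, prs, list("All-tasks" = .task_names))
}

#' Select the feature columns of one model
#'
#' Returns the STGF columns of the model's tasks plus the dual-task-cost
#' columns of any included dual task; non-feature columns (`id`, `group`,
#' `label`) are carried through when present.
#'
#' @param table a feature table (e.g. from [assemble_feature_table()] or
#'   [generate_feature_table()]).
#' @param model a model id from [enumerate_models()].
#' @return The column subset of `table` for that model.
#' @export
select_model_columns <- function(table, model) {
  models <- enumerate_models()
  if (!model %in% names(models))
    stop_gaitssc("unknown model '%s' (known: %s)", model,
                 paste(names(models), collapse = ", "))
  tasks <- models[[model]]
  cols <- c(as.vector(t(outer(tasks, .stgf_names, paste, sep = "::"))),
            unlist(lapply(intersect(.dual_tasks, tasks), function(tk)
              paste("dtc", tk, .stgf_names, sep = "::"))))
  keep <- intersect(c("id", "group", "label"), names(table))
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop_gaitssc("table lacks %d columns of model '%s' (e.g. %s)",
                 length(missing), model, missing[1])
  table[, c(keep, cols), drop = FALSE]
}
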