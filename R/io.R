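#' Write / read a tri-axial recording as delimited text
#'
#' Plain CSV with header `t,ax,ay,az` (seconds and g); device x, y, z are
#' the anteroposterior, mediolateral and vertical axes unless a different
#' `mapping` is given at read time.
#'
#' @param rec an [acceleration_recording()].
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [acceleration_recording()].
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(t = rec$t, ax = rec$ap, ay = rec$ml, az = rec$vt)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param mapping signed axis permutation passed to [transform_axes()].
#' @param sampling_rate Hz; inferred from the timestamps when omitted.
#' @param subject_id,task labels attached to the recording.
#' @export
read_recording <- function(path, mapping = c(ap = "+x", ml = "+y", vt = "+z"),
                           sampling_rate = NULL, subject_id = NA_character_,
                           task = NA_character_) {
  df <- read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop_gaitssc("%s: expected columns t,ax,ay,az (got: %s)", path,
                 paste(names(df), collapse = ","))
  if (nrow(df) < 2L) stop_gaitssc("%s: fewer than 2 samples", path)
  for (cl in need) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop_gaitssc("%s: malformed numeric data at line %d", path, bad[1] + 1L)
  fs <- sampling_rate %||% (1 / median(diff(df$t)))
  rec <- transform_axes(df[, need], mapping, sampling_rate = fs)
  attr(rec, "subject_id") <- subject_id
  attr(rec, "task") <- task
  rec
}

#' Write / read gait events as CSV (`event,time,foot`)
#'
#' @param events a [gait_events()] object or a data frame with columns
#'   `event`, `time`, `foot`.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` a data
#'   frame.
#' @export
write_events <- function(events, path) {
  if (inherits(events, "gait_events")) {
    events <- rbind(
      data.frame(event = "IC", time = events$ic_times, foot = events$ic_foot),
      data.frame(event = "FC", time = events$fc_times, foot = events$fc_foot))
    events <- events[order(events$time), ]
  }
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("event", "time", "foot") %in% names(df)))
    stop_gaitssc("%s: expected columns event,time,foot", path)
  df
}

#' Write / read a feature table as CSV
#'
#' The `<task>::<stgf>` column-naming contract survives the round trip
#' (`check.names` is disabled on read).
#'
#' @param table feature table data frame.
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the data frame.
#' @export
write_feature_table <- function(table, path) {
  df <- cbind(id = rownames(table), table)
  if ("id" %in% names(table)) df <- table
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
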