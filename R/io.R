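#' Read and write pipeline CSV files
#'
#' Plain-CSV interchange for the pipeline's observables, with fixed headers:
#' time courses (`time_min, pe_fraction[, replicate_id]`), activity series
#' (`time_min, rel_activity`), trajectories (`traj_id, frame, time_s,
#' intensity_donor, intensity_acceptor`) and binding events (`traj_id,
#' start_s, end_s, dwell_s, mean_E, left_censored, right_censored`).
#' All files are comma-separated, `.` decimal, UTF-8.
#'
#' @param x Data frame to write (or, for events, an `"event_set"`).
#' @param path File path.
#' @return Readers return a data frame; writers return `path` invisibly.
#' @name pipeline_io
NULL

.read_csv_checked <- function(path, required) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}

#' @rdname pipeline_io
#' @export
read_timecourse <- function(path) .read_csv_checked(path, c("time_min", "pe_fraction"))

#' @rdname pipeline_io
#' @export
write_timecourse <- function(x, path) {
  stopifnot(all(c("time_min", "pe_fraction") %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_activity <- function(path) .read_csv_checked(path, c("time_min", "rel_activity"))

#' @rdname pipeline_io
#' @export
write_activity <- function(x, path) {
  stopifnot(all(c("time_min", "rel_activity") %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_trajectories <- function(path) {
  .read_csv_checked(path, c("traj_id", "frame", "time_s",
                            "intensity_donor", "intensity_acceptor"))
}

#' @rdname pipeline_io
#' @export
write_trajectories <- function(x, path) {
  stopifnot(all(c("traj_id", "frame", "time_s",
                  "intensity_donor", "intensity_acceptor") %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_events <- function(path) {
  .read_csv_checked(path, c("traj_id", "start_s", "end_s", "dwell_s",
                            "mean_E", "left_censored", "right_censored"))
}

#' @rdname pipeline_io
#' @export
write_events <- function(x, path) {
  if (inherits(x, "event_set")) x <- x$events
  stopifnot(all(c("traj_id", "start_s", "end_s", "dwell_s", "mean_E",
                  "left_censored", "right_censored") %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
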