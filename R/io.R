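#' Read/write the session container
#'
#' A session (tensor + trial table + any decomposition) is stored as one
#' self-describing RDS container; the trial table and event lists are
#' additionally exportable as plain CSV for interoperability.
#'
#' @param x list with at least `session` and `trials` (as returned by
#'   [simulate_session()]), optionally `decomp`.
#' @param path file path.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the stored list.
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x$session, "session_tensor"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) readRDS(path)

#' Export/import a trial table as CSV
#'
#' The list column of saccade times is flattened to a semicolon-separated
#' string. Columns: trial, theta, difficulty, left_angle, right_angle,
#' choice, correct, first_move_time, first_move_dir, pupil_change,
#' attention, saccades.
#'
#' @param trials trial table data.frame.
#' @param path CSV file path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` the reconstructed data.frame.
#' @export
write_trials_csv <- function(trials, path) {
  out <- trials
  out$saccades <- vapply(trials$saccades, function(s)
    paste(format(s, digits = 10, trim = TRUE), collapse = ";"), character(1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$saccades <- lapply(strsplit(ifelse(is.na(df$saccades), "",
                                        df$saccades), ";"),
                        function(s) as.numeric(s[nzchar(s)]))
  df
}

#' Export an event list as CSV
#'
#' Columns: kind, time_s, direction (wheel) or magnitude (saccades),
#' duration_ms.
#' @param events an `event_list` (see [detect_wheel_movements()]).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- as.data.frame(events$events)
  df <- cbind(kind = events$kind, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a pipeline configuration as YAML
#' @param config a named list (see [default_config()]).
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
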