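# Log export: per-frame tracking records as CSV, run summaries as JSON.

#' Write a per-frame tracking record to CSV
#'
#' @param run A `track_run` from [run_tracking()], or its `record`
#'   `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_record <- function(run, path) {
  rec <- if (inherits(run, "track_run")) run$record else run
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' Records tracking duration, mean/sd error and loss events in a small
#' machine-readable file.
#'
#' @param run A `track_run` from [run_tracking()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(run, path) {
  stopifnot(inherits(run, "track_run"))
  jsonlite::write_json(run$summary, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
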