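# CSV / JSON readers and writers for traces, events and run summaries.
# Dialect: comma-separated, UTF-8, "." decimal, header row.

TRACE_COLUMNS <- c("time_s", "lat_pos_m", "lane_index", "steer_angle_rad",
                   "phi", "speed_kmh", "long_pos_m")

#' Write a driving trace to CSV
#'
#' @param trace Trace data.frame (see [sim_block()]).
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  missing <- setdiff(TRACE_COLUMNS, names(trace))
  if (length(missing))
    stop("trace lacks columns: ", paste(missing, collapse = ", "))
  utils::write.csv(trace[, TRACE_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a driving trace from CSV
#'
#' @param path CSV written by [write_trace_csv()] (or any file with the
#'   trace columns).
#' @return Trace data.frame.
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path)
  missing <- setdiff(TRACE_COLUMNS, names(tr))
  if (length(missing))
    stop("trace file lacks columns: ", paste(missing, collapse = ", "))
  tr
}

#' Write an experiment summary to JSON
#'
#' @param run An `experiment_run` from [run_experiment()].
#' @param path Output path.
#' @export
write_summary_json <- function(run, path) {
  obj <- list(variant = run$variant, master_seed = run$master_seed,
              replicates = run$replicates, summary = run$summary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a pupil CSV
#'
#' Expects columns `time_s`, `diameter`; blink and fixation intervals come
#' from companion CSVs with `start`, `end` columns.
#'
#' @param path Pupil samples CSV.
#' @param blinks_path,fixations_path Optional interval CSVs.
#' @return A [pupil_trace()].
#' @export
read_pupil_csv <- function(path, blinks_path = NULL, fixations_path = NULL) {
  d <- utils::read.csv(path)
  rd <- function(p) if (is.null(p)) NULL else utils::read.csv(p)
  pupil_trace(d$time_s, d$diameter, rd(blinks_path), rd(fixations_path))
}
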