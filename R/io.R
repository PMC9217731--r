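# Run artifacts: event log as JSONL, per-epoch metrics as CSV, and a
# manifest (configuration + seed) written next to every output so each
# run is replayable.

#' Write a run's event log as JSONL
#'
#' One JSON object per event, in simulation order.
#'
#' @param run A `fed_run`.
#' @param path File path.
#' @export
write_runlog <- function(run, path) {
  stopifnot(inherits(run, "fed_run"))
  ev <- run$events
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    jsonlite::toJSON(list(sim_time = ev$sim_time[i], kind = ev$kind[i],
                          device = ev$device[i], epoch = ev$epoch[i]),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run's per-epoch metrics as CSV
#'
#' @param run A `fed_run`.
#' @param path File path.
#' @export
write_metrics_csv <- function(run, path) {
  stopifnot(inherits(run, "fed_run"))
  utils::write.csv(run$metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' @param run A `fed_run`.
#' @param path File path.
#' @export
write_manifest <- function(run, path) {
  stopifnot(inherits(run, "fed_run"))
  jsonlite::write_json(list(
    algo = run$algo,
    n_devices = run$n_devices,
    T = run$T,
    seed = run$seed,
    config = run$config[!vapply(run$config, is.function, logical(1))]
  ), path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
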