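#' Write and read simulation traces
#'
#' Traces are written as plain CSV in tidy wide format (one row per
#' sampled time; columns `time` in ms, all state variables, all currents
#' in A/F and SR fluxes in mM/ms) with a fixed, stable column order.
#'
#' @param trace `hfcell_trace`.
#' @param path file path.
#' @return `read_trace()` returns the trace data.frame.
#' @export
write_trace <- function(trace, path) {
  cols <- c("time", .state_names, .current_names)
  write.csv(trace[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- read.csv(path)
  class(tr) <- c("hfcell_trace", "data.frame")
  tr
}

#' Write biomarker rows
#'
#' Tidy CSV keyed by condition and frequency, one row per measured beat.
#'
#' @param biomarkers data.frame of biomarker rows (see [biomarker_set()]),
#'   with optional `condition` and `frequency` columns prepended.
#' @param path file path.
#' @export
write_biomarkers <- function(biomarkers, path) {
  write.csv(biomarkers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sensitivity matrix
#'
#' Writes the long table (`<path>`) and the wide normalized matrix
#' (`<path base>_wide.csv`).
#'
#' @param sens `hfcell_sensitivity` from [build_matrix()].
#' @param path file path for the long CSV.
#' @export
write_sensitivity <- function(sens, path) {
  write.csv(sens$long, path, row.names = FALSE, quote = FALSE)
  wide <- sub("\\.csv$", "_wide.csv", path)
  write.csv(data.frame(characteristic = rownames(sens$matrix),
                       sens$matrix, check.names = FALSE),
            wide, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON manifest echoing the configuration together with run statistics
#' (beats paced, which steady-state criterion fired, solver settings) and
#' the package version, so a run can be reproduced from its outputs.
#'
#' @param path file path.
#' @param config `hfcell_config` used for the run.
#' @param stats named list of run statistics.
#' @export
write_manifest <- function(path, config, stats = list()) {
  manifest <- list(
    package = "hfcell",
    version = as.character(utils::packageVersion("hfcell")),
    config = unclass(config),
    stats = stats
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
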