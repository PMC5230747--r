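#' Save a state trace as plain text
#'
#' Writes `<prefix>_wires.csv` and `<prefix>_transistors.csv` (time-major
#' 0/1 matrices with id column headers) plus `<prefix>_meta.json` holding
#' the wire/transistor id order and any annotations passed in `meta`.
#'
#' @param trace a `state_trace`.
#' @param prefix output path prefix.
#' @param meta named list of annotations (fixture name, seed, lesions,
#'   stimulus digest, ...).
#' @return `prefix`, invisibly.
#' @export
write_trace <- function(trace, prefix, meta = list()) {
  utils::write.csv(trace$wire_values, paste0(prefix, "_wires.csv"),
                   row.names = FALSE)
  utils::write.csv(trace$transistor_on, paste0(prefix, "_transistors.csv"),
                   row.names = FALSE)
  meta$wire_ids <- as.integer(colnames(trace$wire_values))
  meta$transistor_ids <- as.integer(colnames(trace$transistor_on))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Load a state trace saved by [write_trace()]
#'
#' @param prefix path prefix used when writing.
#' @param netlist optional `netlist` to re-attach.
#' @return a `state_trace` (without a netlist unless supplied).
#' @export
read_trace <- function(prefix, netlist = NULL) {
  wv <- as.matrix(utils::read.csv(paste0(prefix, "_wires.csv"),
                                  check.names = FALSE))
  tv <- as.matrix(utils::read.csv(paste0(prefix, "_transistors.csv"),
                                  check.names = FALSE))
  storage.mode(wv) <- "integer"
  storage.mode(tv) <- "integer"
  structure(list(wire_values = wv, transistor_on = tv, netlist = netlist),
            class = "state_trace")
}

#' Save spike times as CSV (unit, time long format)
#' @param spikes a `spike_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(as_tibble.spike_set(spikes), path, row.names = FALSE)
  invisible(path)
}

#' Save a tuning classification table as CSV
#' @param classified output of [classify_units()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning <- function(classified, path) {
  utils::write.csv(classified, path, row.names = FALSE)
  invisible(path)
}

#' Save NMF factors and component correlations as CSV
#' @param fit a `factorization`.
#' @param interp optional `component_interpretation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_factorization <- function(fit, interp = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$W, file.path(dir, "W.csv"), row.names = FALSE)
  utils::write.csv(fit$H, file.path(dir, "H.csv"), row.names = FALSE)
  if (!is.null(interp)) {
    utils::write.csv(interp$correlations,
                     file.path(dir, "signal_correlations.csv"))
    utils::write.csv(interp$dominant,
                     file.path(dir, "dominant_components.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
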