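#' Read and write spike-time tables
#'
#' Spike tables are plain CSV with columns `electrode_id`, `time_s`; the
#' recording duration and electrode count travel in a JSON sidecar
#' (`<path>.json`) so silent electrodes are not lost.
#'
#' @param spikes A [spike_trains] tibble.
#' @param path CSV file path.
#' @return `read_spike_csv` returns a [spike_trains] tibble.
#' @export
write_spike_csv <- function(spikes, path) {
  utils::write.csv(tibble::as_tibble(spikes)[c("electrode_id", "time_s")],
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(duration_s = attr(spikes, "duration_s"),
         n_electrodes = attr(spikes, "n_electrodes")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param duration_s,n_electrodes Used when no JSON sidecar is present.
#' @export
read_spike_csv <- function(path, duration_s = NULL, n_electrodes = NULL) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    duration_s <- duration_s %||% meta$duration_s
    n_electrodes <- n_electrodes %||% meta$n_electrodes
  }
  if (is.null(duration_s)) abort("no duration_s: supply it or provide the JSON sidecar.")
  spike_trains(df, duration_s, n_electrodes)
}

#' Read and write raw voltage recordings
#'
#' Recordings are serialized as a CSV matrix (electrodes x samples, one row
#' per electrode, no header) with a JSON metadata sidecar holding `fs_hz`,
#' `div_day` and `well_id`.
#'
#' @param raw A `raw_recording`.
#' @param path CSV file path.
#' @return `read_recording` returns a `raw_recording`.
#' @export
write_recording <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"))
  utils::write.table(raw$voltage_uV, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs_hz = raw$fs_hz, div_day = raw$div_day,
                            well_id = raw$well_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(voltage_uV = v, fs_hz = meta$fs_hz,
                 div_day = as.integer(meta$div_day %||% NA),
                 well_id = meta$well_id %||% "unknown"),
            class = "raw_recording")
}

#' Read and write fluorescence trace matrices
#'
#' Cells x samples CSV (one row per cell, no header) with `fs_hz` in a JSON
#' sidecar.
#'
#' @param F Cells x samples numeric matrix.
#' @param fs_hz Sampling rate (Hz).
#' @param path CSV file path.
#' @return `read_traces` returns a list with `F` and `fs_hz`.
#' @export
write_traces <- function(F, fs_hz, path) {
  utils::write.table(F, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs_hz = fs_hz), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  F <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(F) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(F = F, fs_hz = meta$fs_hz)
}
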