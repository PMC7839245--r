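#' Write / read a ventilation pattern file
#'
#' Pattern files are tab-separated with a header and three columns
#' (breath_index, pressure_ratio, period_ratio); ratios are written with
#' full double precision (17 significant digits) so read/write round-trips
#' are bit-exact. A JSON sidecar `<path>.json` carries the source metadata
#' and an MD5 checksum of the table, verified on read.
#'
#' @param pattern A `ventilation_pattern`.
#' @param path Output file path.
#' @return `write_pattern`: the path, invisibly. `read_pattern`: the
#'   `ventilation_pattern`.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "ventilation_pattern"))
  df <- pattern$entries
  lines <- c("breath_index\tpressure_ratio\tperiod_ratio",
             sprintf("%d\t%.17g\t%.17g", df$breath_index,
                     df$pressure_ratio, df$period_ratio))
  writeLines(lines, path)
  sidecar <- list(
    format = "pvvent_pattern/1", n_breaths = pattern$n_breaths,
    source_meta = pattern$source_meta,
    checksum_md5 = unname(tools::md5sum(path))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else NULL
  if (!is.null(meta$checksum_md5) &&
      !identical(unname(tools::md5sum(path)), meta$checksum_md5))
    pv_stop("pattern file checksum mismatch", "pvvent_io_error")
  df <- utils::read.delim(path)
  structure(
    list(entries = df, n_breaths = nrow(df),
         source_meta = meta$source_meta %||% list()),
    class = "ventilation_pattern"
  )
}

#' Write / read a plethysmograph recording
#'
#' Tab-separated time/value table plus a JSON sidecar holding the sampling
#' rate, units and artifact intervals.
#'
#' @param recording A [pleth_recording()].
#' @param path Output file path.
#' @param units Amplitude units recorded in the sidecar.
#' @export
write_recording <- function(recording, path, units = "a.u.") {
  stopifnot(inherits(recording, "pleth_recording"))
  t <- (seq_along(recording$samples) - 1) / recording$sampling_rate
  writeLines(c("time_s\tvalue",
               sprintf("%.17g\t%.17g", t, recording$samples)), path)
  iv <- recording$artifact_intervals
  sidecar <- list(
    format = "pvvent_recording/1",
    sampling_rate_hz = recording$sampling_rate, units = units,
    artifact_start_s = iv[, 1], artifact_end_s = iv[, 2]
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(path)
  iv <- if (length(meta$artifact_start_s)) {
    cbind(as.numeric(meta$artifact_start_s), as.numeric(meta$artifact_end_s))
  } else NULL
  pleth_recording(df$value, as.numeric(meta$sampling_rate_hz), iv)
}

#' Write / read an impedance spectrum table
#'
#' Tab-separated (frequency_hz, z_real, z_imag, coherence) with a JSON
#' sidecar describing units and provenance.
#'
#' @param spectrum An `impedance_spectrum`.
#' @param path Output file path.
#' @param meta Optional list merged into the sidecar.
#' @export
write_impedance <- function(spectrum, path, meta = list()) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  writeLines(c("frequency_hz\tz_real\tz_imag\tcoherence",
               sprintf("%.17g\t%.17g\t%.17g\t%.17g", spectrum$frequency,
                       spectrum$z_real, spectrum$z_imag,
                       spectrum$coherence)), path)
  sidecar <- c(list(format = "pvvent_impedance/1",
                    units = "cmH2O.s/L"), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_impedance
#' @export
read_impedance <- function(path) {
  df <- utils::read.delim(path)
  impedance_spectrum(df$frequency_hz, df$z_real, df$z_imag, df$coherence)
}
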