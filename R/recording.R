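#' Single-channel recording container
#'
#' A uniformly sampled single-channel time series, e.g. the source
#' reconstructed activity of a cortical region of interest. Optionally
#' carries a ground-truth event table when the recording was simulated.
#'
#' @param samples numeric vector of signal values (arbitrary source units).
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param truth_events optional `data.frame` with columns `onset_s`,
#'   `offset_s`, `peak_amplitude` describing simulated burst events.
#' @return an object of class `ts_recording` with fields `samples`, `fs`,
#'   `subject_id`, `truth_events`.
#' @export
ts_recording <- function(samples, fs, subject_id = "s01", truth_events = NULL) {
  assert_scalar_pos(fs, "fs")
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop_invalid("`samples` must be a numeric vector without missing values")
  }
  if (!is.null(truth_events)) {
    truth_events <- as.data.frame(truth_events)
    stopifnot(all(c("onset_s", "offset_s", "peak_amplitude") %in%
                    names(truth_events)))
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         subject_id = as.character(subject_id), truth_events = truth_events),
    class = "ts_recording"
  )
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  if (!is.null(x$truth_events)) {
    cat(sprintf("  %d ground-truth events\n", nrow(x$truth_events)))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x a `ts_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(x) length(x$samples) / x$fs

#' Write a recording to disk
#'
#' Two formats are supported: `"tsv"` writes a two-column delimited text
#' file (`time_s`, `value`); `"raw"` writes a little-endian float64 array
#' plus a JSON sidecar header (`<path>.json`) holding `fs` and
#' `subject_id`.
#'
#' @param x a `ts_recording`.
#' @param path output file path.
#' @param format `"tsv"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, format = c("tsv", "raw")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- data.frame(time_s = (seq_along(x$samples) - 1) / x$fs,
                    value = x$samples)
    utils::write.table(d, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(x$samples, con, size = 8, endian = "little")
    jsonlite::write_json(
      list(fs = x$fs, subject_id = x$subject_id,
           n_samples = length(x$samples)),
      paste0(path, ".json"), auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path. A `<path>.json` sidecar marks the raw format.
#' @param fs sampling rate, required for `"tsv"` files (it is recovered
#'   from the time column when omitted).
#' @param subject_id subject identifier for `"tsv"` files.
#' @return a `ts_recording`.
#' @export
read_recording <- function(path, fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop_data("recording not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    hdr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    con <- file(path, "rb")
    on.exit(close(con))
    samples <- readBin(con, "double", n = hdr$n_samples, size = 8,
                       endian = "little")
    return(ts_recording(samples, hdr$fs,
                        subject_id %||% hdr$subject_id))
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(fs)) {
    dt <- diff(d$time_s[1:2])
    fs <- 1 / dt
  }
  ts_recording(d$value, fs, subject_id %||% sub("\\..*$", "", basename(path)))
}
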