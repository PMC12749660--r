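#' Construct an EEG recording object
#'
#' A light container for a multichannel EEG trace: a channels-by-samples
#' numeric matrix plus sampling rate and channel labels. Signal matrices stay
#' matrices (the natural container for filtering and spectral work); every
#' analysis result derived from them is returned as a tibble.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of channel names, one per row of `data`.
#'   Labels are canonicalized via [canonical_labels()].
#' @param reference Reference state, `"raw"` or `"car"`.
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2), fs = 100, labels = c("Cz", "Pz"))
#' rec
eeg_recording <- function(data, fs, labels = NULL, reference = c("raw", "car")) {
  reference <- match.arg(reference)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_field("data", "must be a numeric channels x samples matrix")
  }
  if (!all(is.finite(data))) abort_field("data", "all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort_field("fs", "sampling rate must be a positive scalar (Hz)")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- canonical_labels(as.character(labels))
  if (length(labels) != nrow(data)) {
    abort_field("labels", "one label per channel required")
  }
  if (anyDuplicated(labels)) abort_field("labels", "labels must be unique")
  structure(
    list(data = data, fs = fs, labels = labels, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s, ref: %s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference
  ))
  cat("channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [eeg_recording()].
#' @return Scalar seconds.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$data) / rec$fs
}

#' Write / read a recording as TSV matrix plus JSON sidecar
#'
#' The interchange format for EEG fixtures: a plain tab-separated numeric
#' matrix (one row per channel) and a JSON sidecar holding labels, sampling
#' rate and reference state.
#'
#' @param rec An [eeg_recording()].
#' @param path Path of the matrix TSV; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(labels = rec$labels, fs = rec$fs, reference = rec$reference),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  eeg_recording(m, fs = side$fs, labels = side$labels,
                reference = if (identical(side$reference, "car")) "car" else "raw")
}
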