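#' Multichannel EEG recording container
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels channel labels (length `nrow(data)`).
#' @param cycle_onsets integer sample indices (1-based) of SWIFT cycle
#'   starts, or `NULL`.
#' @return an object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, cycle_onsets = NULL) {
  if (!is.matrix(data)) stop("`data` must be a channels x samples matrix")
  if (anyNA(data) || any(!is.finite(data))) stop("`data` contains non-finite values")
  labels <- labels %||% paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (!is.null(cycle_onsets)) {
    cycle_onsets <- as.integer(cycle_onsets)
    if (any(cycle_onsets < 1L) || any(cycle_onsets > ncol(data)))
      stop("`cycle_onsets` outside the recording")
  }
  dimnames(data) <- NULL
  structure(list(data = data, fs = fs, labels = labels,
                 cycle_onsets = cycle_onsets,
                 duration_s = ncol(data) / fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(x$duration_s, 3), " s)",
      if (!is.null(x$cycle_onsets))
        paste0(", ", length(x$cycle_onsets), " cycles"),
      "\n", sep = "")
  invisible(x)
}

# sample-index ranges of each cycle: onset_k .. onset_{k+1}-1 (last cycle
# runs to the end of the recording)
cycle_ranges <- function(rec) {
  on <- rec$cycle_onsets
  if (is.null(on)) stop("recording carries no cycle onsets")
  ends <- c(on[-1] - 1L, ncol(rec$data))
  Map(function(a, b) a:b, on, ends)
}

#' Write / read a recording as plain text
#'
#' The canonical on-disk form is a TSV sample matrix (one row per channel)
#' plus a JSON sidecar holding the sampling rate, channel labels and cycle
#' onsets.
#'
#' @param rec an `"eeg_recording"`.
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `"eeg_recording"`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  data.table::fwrite(data.table::as.data.table(rec$data),
                     paste0(path, ".tsv"), sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, labels = rec$labels,
         cycle_onsets = rec$cycle_onsets),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  mat <- as.matrix(data.table::fread(paste0(path, ".tsv"), header = FALSE))
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_recording(mat, fs = as.numeric(meta$fs), labels = meta$labels,
                cycle_onsets = meta$cycle_onsets)
}
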