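#' Construct a seizure iEEG recording
#'
#' Container for a single seizure clip: a channels-by-samples voltage matrix
#' plus the metadata needed by the preprocessing and connectivity stages.
#' Sample indices are 1-based; `termination_sample` is exclusive, so the
#' seizure occupies samples `onset_sample, ..., termination_sample - 1` and
#' its duration is `(termination_sample - onset_sample) / fs` seconds.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling frequency in Hz.
#' @param onset_sample 1-based index of the first seizure sample.
#' @param termination_sample 1-based exclusive index of seizure end.
#' @param missing_mask logical matrix of the same shape as `data`; `TRUE`
#'   marks samples that are missing (dropouts, artefacts). Defaults to all
#'   `FALSE`.
#' @param channel_labels character vector of channel names.
#' @param excluded_channels character vector of channel labels excluded from
#'   analysis (e.g. visually identified noisy channels, supplied as an input
#'   list).
#'
#' @return An object of class `seizure_recording`.
#' @export
seizure_recording <- function(data, fs,
                              onset_sample = 1L,
                              termination_sample = ncol(data) + 1L,
                              missing_mask = NULL,
                              channel_labels = NULL,
                              excluded_channels = character()) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  n <- nrow(data)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(n))
  }
  stopifnot(length(channel_labels) == n)
  if (is.null(missing_mask)) {
    missing_mask <- matrix(FALSE, n, ncol(data))
  }
  stopifnot(identical(dim(missing_mask), dim(data)), is.logical(missing_mask))
  onset_sample <- as.integer(onset_sample)
  termination_sample <- as.integer(termination_sample)
  if (termination_sample <= onset_sample) {
    stop("termination_sample must be greater than onset_sample")
  }
  stopifnot(all(excluded_channels %in% channel_labels))
  structure(
    list(
      data = data,
      fs = fs,
      onset_sample = onset_sample,
      termination_sample = termination_sample,
      missing_mask = missing_mask,
      channel_labels = channel_labels,
      excluded_channels = excluded_channels
    ),
    class = "seizure_recording"
  )
}

#' Seizure duration in seconds
#'
#' @param rec a [seizure_recording()].
#' @return numeric scalar, `(termination_sample - onset_sample) / fs`.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "seizure_recording"))
  (rec$termination_sample - rec$onset_sample) / rec$fs
}

# indices of channels retained for analysis
analysis_channels <- function(rec) {
  which(!(rec$channel_labels %in% rec$excluded_channels))
}

#' @export
print.seizure_recording <- function(x, ...) {
  cat(sprintf(
    "<seizure_recording> %d channels x %d samples @ %g Hz, duration %.2f s",
    nrow(x$data), ncol(x$data), x$fs, recording_duration(x)
  ), "\n")
  if (length(x$excluded_channels)) {
    cat("  excluded:", paste(x$excluded_channels, collapse = ", "), "\n")
  }
  n_miss <- sum(x$missing_mask)
  if (n_miss > 0) cat(sprintf("  missing samples: %d\n", n_miss))
  invisible(x)
}
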