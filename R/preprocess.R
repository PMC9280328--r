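#' Line length of a signal segment
#'
#' Mean absolute first difference,
#' \deqn{L = \frac{1}{T-1} \sum_{i=1}^{T-1} |x_{i+1} - x_i|,}
#' near zero for flat (dropout) signal.
#'
#' @param x numeric vector with at least 2 samples.
#' @return non-negative scalar.
#' @export
line_length <- function(x) {
  if (length(x) < 2) stop("line length needs at least 2 samples")
  mean(abs(diff(x)))
}

#' Detect signal-dropout windows by line length
#'
#' Slides a short window over the recording, computes per-channel line
#' length, and flags windows in which at least `min_flat_channels` channels
#' are flat (line length at or below `ll_thresh`). The windows immediately
#' preceding and following a flagged window are flagged as well, and the
#' window flags are mapped back to a per-sample missing mask.
#'
#' The channel threshold defaults to half the montage rounded up
#' (8 of 16 channels), the rule used for chronic 16-electrode implants.
#'
#' @param rec a [seizure_recording()].
#' @param win,step window length and step in seconds (defaults 1/10 s and
#'   1/20 s, i.e. 50% overlap).
#' @param ll_thresh line-length threshold below which a channel counts as
#'   flat.
#' @param min_flat_channels number of flat channels required to flag a
#'   window; default `ceiling(n / 2)`.
#'
#' @return list with `window_flags` (logical per window), `window_starts`
#'   (1-based sample index of each window), and `rec`: the input recording
#'   with `missing_mask` set to `TRUE` for all samples of flagged windows.
#' @export
detect_dropout_windows <- function(rec, win = 0.1, step = 0.05,
                                   ll_thresh = 0.5,
                                   min_flat_channels = NULL) {
  stopifnot(inherits(rec, "seizure_recording"))
  chans <- analysis_channels(rec)
  n <- length(chans)
  min_flat_channels <- min_flat_channels %||% ceiling(n / 2)
  L <- round(win * rec$fs)
  stp <- round(step * rec$fs)
  nsamp <- ncol(rec$data)
  if (nsamp < L) stop("recording shorter than one dropout-detection window")
  starts <- seq(1L, nsamp - L + 1L, by = stp)
  flat_counts <- vapply(starts, function(s0) {
    seg <- rec$data[chans, s0:(s0 + L - 1L), drop = FALSE]
    sum(apply(seg, 1, line_length) <= ll_thresh)
  }, numeric(1))
  flags <- flat_counts >= min_flat_channels
  # neighbours of flagged windows are missing too
  ext <- flags
  ext[which(flags) - 1L] <- TRUE
  idx_after <- which(flags) + 1L
  ext[idx_after[idx_after <= length(ext)]] <- TRUE
  mask <- rec$missing_mask
  for (w in which(ext)) {
    mask[, starts[w]:(starts[w] + L - 1L)] <- TRUE
  }
  rec$missing_mask <- mask
  list(window_flags = ext, window_starts = starts, rec = rec)
}

#' Linearly interpolate short missing segments
#'
#' Per-channel runs of missing samples shorter than `max_gap_s` seconds are
#' filled by linear interpolation between the flanking good samples and
#' unmasked. Longer gaps, and gaps touching the recording edges (which would
#' require extrapolation), are left untouched.
#'
#' @param rec a [seizure_recording()].
#' @param max_gap_s maximum gap length (in seconds, exclusive) eligible for
#'   interpolation.
#' @return the recording with short gaps filled.
#' @export
interpolate_short_gaps <- function(rec, max_gap_s = 0.05) {
  stopifnot(inherits(rec, "seizure_recording"))
  max_len <- max_gap_s * rec$fs
  nsamp <- ncol(rec$data)
  for (ch in seq_len(nrow(rec$data))) {
    miss <- rec$missing_mask[ch, ]
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len >= max_len) next
      a <- starts[k] - 1L
      b <- ends[k] + 1L
      if (a < 1L || b > nsamp) next  # edge gap: no extrapolation
      gap <- starts[k]:ends[k]
      rec$data[ch, gap] <- approx(
        x = c(a, b), y = rec$data[ch, c(a, b)], xout = gap
      )$y
      rec$missing_mask[ch, gap] <- FALSE
    }
  }
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over non-excluded channels from each
#' non-excluded channel. Idempotent; after referencing, the per-sample mean
#' across analysis channels is zero.
#'
#' @param rec a [seizure_recording()] with at least two analysis channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "seizure_recording"))
  chans <- analysis_channels(rec)
  if (length(chans) < 2) {
    stop("common average reference requires at least 2 channels")
  }
  avg <- colMeans(rec$data[chans, , drop = FALSE])
  rec$data[chans, ] <- sweep(rec$data[chans, , drop = FALSE], 2, avg)
  rec
}

#' Zero-phase Butterworth bandpass and notch filtering
#'
#' Applies a fourth-order Butterworth bandpass (1-150 Hz by default) and
#' fourth-order band-stop notches of total width `notch_width` centred on
#' each mains harmonic, all run forward-backward (`filtfilt`) for zero phase
#' distortion; the effective magnitude response is therefore eighth-order.
#'
#' @param rec a [seizure_recording()].
#' @param band numeric length-2 passband edges in Hz.
#' @param notch_freqs mains harmonics to notch, e.g. `c(50, 100, 150)` or
#'   `c(60, 120)`; empty for none.
#' @param notch_width total stop-band width in Hz.
#' @param order filter order (applied twice by filtfilt).
#' @return the filtered recording.
#' @export
filter_recording <- function(rec, band = c(1, 150),
                             notch_freqs = c(50, 100, 150),
                             notch_width = 2, order = 4) {
  stopifnot(inherits(rec, "seizure_recording"))
  fs <- rec$fs
  if (fs <= 2 * band[2]) {
    stop("sampling rate too low for the requested passband")
  }
  nyq <- fs / 2
  bp <- signal::butter(order, band / nyq, type = "pass")
  filt <- function(x) signal::filtfilt(bp, x)
  notches <- lapply(notch_freqs[notch_freqs + notch_width / 2 < nyq],
                    function(f0) {
    signal::butter(order, c(f0 - notch_width / 2, f0 + notch_width / 2) / nyq,
                   type = "stop")
  })
  for (ch in seq_len(nrow(rec$data))) {
    x <- filt(rec$data[ch, ])
    for (nf in notches) x <- signal::filtfilt(nf, x)
    rec$data[ch, ] <- x
  }
  rec
}

#' Downsample a set of recordings to their lowest sampling frequency
#'
#' When a subject's seizures were recorded at different sampling rates, all
#' recordings are resampled (with antialiasing) to the minimum rate so that
#' the connectivity windows share one frequency grid.
#'
#' @param recordings list of [seizure_recording()] objects.
#' @return list of recordings, all at the minimum input `fs`.
#' @export
resample_to_common <- function(recordings) {
  stopifnot(is.list(recordings), length(recordings) >= 1)
  fss <- vapply(recordings, function(r) r$fs, numeric(1))
  fs_min <- min(fss)
  lapply(recordings, function(rec) {
    if (rec$fs == fs_min) return(rec)
    # rational resampling factor
    fr <- MASS::fractions(fs_min / rec$fs, cycles = 8)
    pq <- as.integer(strsplit(attr(fr, "fracs"), "/")[[1]])
    if (length(pq) == 1L) pq <- c(pq, 1L)
    new_len <- NULL
    newdata <- NULL
    for (ch in seq_len(nrow(rec$data))) {
      y <- signal::resample(rec$data[ch, ], p = pq[1], q = pq[2])
      if (is.null(newdata)) {
        new_len <- length(y)
        newdata <- matrix(0, nrow(rec$data), new_len)
      }
      newdata[ch, ] <- y
    }
    scale <- fs_min / rec$fs
    newmask <- matrix(FALSE, nrow(rec$data), new_len)
    if (any(rec$missing_mask)) {
      old_idx <- pmin(ncol(rec$data),
                      pmax(1L, round((seq_len(new_len) - 1) / scale) + 1L))
      newmask <- rec$missing_mask[, old_idx, drop = FALSE]
    }
    seizure_recording(
      newdata, fs = fs_min,
      onset_sample = max(1L, round((rec$onset_sample - 1) * scale) + 1L),
      termination_sample = min(new_len + 1L,
                               round((rec$termination_sample - 1) * scale) + 1L),
      missing_mask = newmask,
      channel_labels = rec$channel_labels,
      excluded_channels = rec$excluded_channels
    )
  })
}
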