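#' Canonical iEEG frequency bands
#'
#' The six bands used for time-varying functional connectivity:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 and
#' high gamma 80-150 Hz. Band membership of FFT bins is half-open
#' (`f1 <= f < f2`) so shared edges are never double-counted.
#'
#' @return A 6 x 2 numeric matrix with rownames, columns `f1`, `f2`.
#' @export
canonical_bands <- function() {
  b <- rbind(
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
    beta = c(13, 30), gamma = c(30, 80), high_gamma = c(80, 150)
  )
  colnames(b) <- c("f1", "f2")
  b
}

#' Construct a connectivity time series ("seizure pathway")
#'
#' One seizure's time-varying functional connectivity: `m` sliding windows,
#' each described by `6 * (n^2 - n) / 2` non-negative features (the
#' vectorized upper triangle of the coherence matrix in each band, L1
#' normalized per band).
#'
#' @param features numeric matrix, windows x features, all entries >= 0.
#' @param n_channels number of channels `n` the features were derived from.
#' @param bands band definition matrix as [canonical_bands()].
#' @param window_times numeric vector of window start times (seconds from
#'   seizure onset).
#' @param missing_windows logical vector, `TRUE` for windows that could not
#'   be computed.
#'
#' @return An object of class `fc_series`.
#' @export
fc_series <- function(features, n_channels, bands = canonical_bands(),
                      window_times = NULL, missing_windows = NULL) {
  stopifnot(is.matrix(features), all(features >= 0 | is.na(features)))
  n_pairs <- n_channels * (n_channels - 1) / 2
  n_bands <- nrow(bands)
  if (ncol(features) != n_bands * n_pairs) {
    stop("feature dimension does not match n_channels and bands")
  }
  m <- nrow(features)
  window_times <- window_times %||% as.numeric(seq_len(m) - 1)
  missing_windows <- missing_windows %||% rep(FALSE, m)
  stopifnot(length(window_times) == m, length(missing_windows) == m)
  structure(
    list(
      features = features,
      n_channels = n_channels,
      bands = bands,
      band_index = rep(seq_len(n_bands), each = n_pairs),
      window_times = window_times,
      missing_windows = missing_windows
    ),
    class = "fc_series"
  )
}

#' @export
print.fc_series <- function(x, ...) {
  cat(sprintf(
    "<fc_series> %d windows x %d features (%d channels, %d bands)%s\n",
    nrow(x$features), ncol(x$features), x$n_channels, nrow(x$bands),
    if (any(x$missing_windows)) {
      sprintf(", %d missing windows", sum(x$missing_windows))
    } else ""
  ))
  invisible(x)
}

# coerce fc_series or plain windows-x-features matrix to a matrix
fc_matrix <- function(x) {
  if (inherits(x, "fc_series")) {
    if (any(x$missing_windows)) {
      stop("fc_series contains missing windows; exclude the seizure first")
    }
    x$features
  } else if (is.matrix(x)) {
    x
  } else {
    stop("expected an fc_series or a windows x features matrix")
  }
}

# L1-normalize each band block of each row; all-zero blocks are left as
# zeros and reported so callers can flag the window rather than divide by 0
normalize_band_blocks <- function(features, band_index) {
  degenerate <- rep(FALSE, nrow(features))
  for (b in unique(band_index)) {
    cols <- band_index == b
    s <- rowSums(features[, cols, drop = FALSE])
    zero <- s <= 0
    s[zero] <- 1
    features[, cols] <- features[, cols, drop = FALSE] / s
    degenerate <- degenerate | zero
  }
  list(features = features, degenerate = degenerate)
}

# Welch band-summed cross-spectral accumulator.
#
# x: samples x channels matrix for one FC window. Returns, per band, the
# n x n matrix of band- and subwindow-summed cross spectra
# sum_f sum_sub X_i(f) X_j(f)*, from which band-averaged coherence is
# formed. Subwindows listed in `drop_sub` are excluded (missing data).
welch_band_cross <- function(x, fs, bands, welch_win = 2, welch_overlap = 1,
                             drop_sub = integer()) {
  nsamp <- nrow(x)
  L <- round(welch_win * fs)
  step <- L - round(welch_overlap * fs)
  if (nsamp < L) stop("window shorter than the Welch subwindow")
  starts <- seq(1L, nsamp - L + 1L, by = step)
  keep <- setdiff(seq_along(starts), drop_sub)
  if (length(keep) == 0L) stop("no usable Welch subwindows")
  # periodic Hamming taper (constants cancel in the coherence ratio)
  taper <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / L)
  freqs <- (seq_len(L) - 1) * fs / L
  bin_sets <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs >= bands[b, 1] & freqs < bands[b, 2] & freqs <= fs / 2)
  })
  if (any(vapply(bin_sets, length, 1L) == 0L)) {
    stop("a frequency band contains no FFT bins at this fs/window length")
  }
  n <- ncol(x)
  acc <- lapply(seq_len(nrow(bands)), function(b) {
    matrix(complex(real = 0), n, n)
  })
  for (s0 in starts[keep]) {
    seg <- x[s0:(s0 + L - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * taper
    X <- stats::mvfft(seg)
    for (b in seq_along(bin_sets)) {
      Xb <- X[bin_sets[[b]], , drop = FALSE]
      acc[[b]] <- acc[[b]] + t(Xb) %*% Conj(Xb)
    }
  }
  acc
}

#' Band-averaged coherence of two signals
#'
#' Coherence formed from band-summed cross- and auto-spectra,
#' \deqn{C_{i,j} = \frac{\left|\sum_{f=f_1}^{f_2} P_{i,j}(f)\right|^2}
#'   {\sum_f P_{i,i}(f) \sum_f P_{j,j}(f)},}
#' with the spectra estimated by Welch's method (2 s subwindows, 1 s
#' overlap, Hamming taper). This is not bin-wise coherence averaged over the
#' band: the spectra are summed first, so the value lies in \[0, 1\] by the
#' Cauchy-Schwarz inequality, with equality for identical signals.
#'
#' @param x,y numeric vectors of equal length (one analysis window each).
#' @param band numeric length-2, band edges `(f1, f2)` in Hz; bins with
#'   `f1 <= f < f2` are used.
#' @param fs sampling frequency in Hz.
#' @param welch_win,welch_overlap Welch subwindow length and overlap in
#'   seconds.
#'
#' @return Coherence in `[0, 1]`.
#' @export
band_coherence <- function(x, y, band, fs, welch_win = 2, welch_overlap = 1) {
  stopifnot(length(x) == length(y), length(band) == 2, band[2] > band[1])
  if (band[2] > fs / 2) stop("band extends beyond the Nyquist frequency")
  acc <- welch_band_cross(cbind(x, y), fs, matrix(band, 1),
                          welch_win, welch_overlap)[[1]]
  p11 <- Re(acc[1, 1]); p22 <- Re(acc[2, 2])
  if (p11 <= 0 || p22 <= 0) return(0)
  min(1, Mod(acc[1, 2])^2 / (p11 * p22))
}

#' Compute a seizure's time-varying functional connectivity
#'
#' Slides a 10 s window (9 s overlap) across the seizure; in each window the
#' coherence matrix is computed per canonical band, its upper triangle
#' vectorized and L1-normalized per band. A seizure of duration `d` seconds
#' yields `m = floor(d) - 9` windows (with the default window/step), each
#' fully inside `[onset, termination)`.
#'
#' Missing-data tolerance: a window is computed from the subset of its 2 s
#' Welch subwindows that contain no missing samples; the window is marked
#' missing only when at least `max_missing_subwindows` subwindows are
#' affected. Set `max_missing_subwindows = 0` to disable tolerance (any
#' missing subwindow makes the window missing).
#'
#' @param rec a [seizure_recording()]; duration must be at least `fc_win`
#'   seconds (seizures shorter than 10 s are not analyzable).
#' @param fc_win,fc_step connectivity window length and step in seconds.
#' @param bands band matrix as [canonical_bands()].
#' @param max_missing_subwindows minimum number of missing 2 s subwindows at
#'   which a connectivity window is declared missing (default 5).
#' @param welch_win,welch_overlap Welch parameters in seconds.
#'
#' @return An [fc_series()] with `m` windows and `6 (n^2 - n)/2` features.
#' @export
compute_fc_series <- function(rec, fc_win = 10, fc_step = 1,
                              bands = canonical_bands(),
                              max_missing_subwindows = 5,
                              welch_win = 2, welch_overlap = 1) {
  stopifnot(inherits(rec, "seizure_recording"))
  dur <- recording_duration(rec)
  if (dur < fc_win) {
    stop(sprintf("seizure duration %.2f s is below the %g s analysis window",
                 dur, fc_win))
  }
  fs <- rec$fs
  chans <- analysis_channels(rec)
  n <- length(chans)
  if (n < 2) stop("need at least two analysis channels")
  m <- floor((dur - fc_win) / fc_step) + 1
  n_pairs <- n * (n - 1) / 2
  n_bands <- nrow(bands)
  feats <- matrix(0, m, n_bands * n_pairs)
  missing <- rep(FALSE, m)
  ut <- upper.tri(matrix(0, n, n))
  L <- round(welch_win * fs)
  sub_step <- L - round(welch_overlap * fs)
  for (k in seq_len(m)) {
    w0 <- rec$onset_sample + round((k - 1) * fc_step * fs)
    idx <- w0:(w0 + round(fc_win * fs) - 1L)
    xw <- t(rec$data[chans, idx, drop = FALSE])
    mask <- rec$missing_mask[chans, idx, drop = FALSE]
    # subwindows (any channel) containing missing samples are dropped
    sub_starts <- seq(1L, nrow(xw) - L + 1L, by = sub_step)
    bad <- which(vapply(sub_starts, function(s0) {
      any(mask[, s0:(s0 + L - 1L)])
    }, logical(1)))
    if (max_missing_subwindows > 0 && length(bad) >= max_missing_subwindows) {
      missing[k] <- TRUE
      next
    }
    if (max_missing_subwindows == 0 && length(bad) > 0) {
      missing[k] <- TRUE
      next
    }
    acc <- welch_band_cross(xw, fs, bands, welch_win, welch_overlap,
                            drop_sub = bad)
    for (b in seq_len(n_bands)) {
      p <- Re(diag(acc[[b]]))
      denom <- outer(p, p)
      C <- Mod(acc[[b]])^2 / pmax(denom, .Machine$double.xmin)
      C <- pmin(C, 1)
      feats[k, ((b - 1) * n_pairs + 1):(b * n_pairs)] <- C[ut]
    }
  }
  band_index <- rep(seq_len(n_bands), each = n_pairs)
  nb <- normalize_band_blocks(feats, band_index)
  missing <- missing | nb$degenerate
  fc_series(nb$features, n_channels = n, bands = bands,
            window_times = (seq_len(m) - 1) * fc_step,
            missing_windows = missing)
}

#' Drop seizures with missing connectivity windows
#'
#' Seizures whose connectivity time series contains one or more missing
#' windows are excluded from downstream analysis; an exclusion log is kept.
#'
#' @param fc_list named list of [fc_series()] objects.
#' @return list with `fc` (the retained series) and `excluded` (character
#'   vector of dropped seizure ids).
#' @export
exclude_incomplete_seizures <- function(fc_list) {
  stopifnot(is.list(fc_list))
  bad <- vapply(fc_list, function(f) any(f$missing_windows), logical(1))
  list(
    fc = fc_list[!bad],
    excluded = names(fc_list)[bad] %||% which(bad)
  )
}
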