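test_that("line length matches its definition", {
  expect_equal(line_length(rep(3.2, 50)), 0)
  expect_equal(line_length(c(0, 1, 0, 1)), 1)
  expect_equal(line_length(c(0, 2, 0)), 2)
  expect_error(line_length(5), "2 samples")
})

test_that("dropout detection applies the half-montage rule with neighbours", {
  set.seed(3)
  base <- matrix(rnorm(16 * 2000, sd = 50), 16)
  fs <- 400
  rec0 <- seizure_recording(matrix(0, 16, 2000), fs)
  det0 <- detect_dropout_windows(rec0)
  expect_true(all(det0$window_flags))

  flat_on <- function(k) {
    r <- seizure_recording(base, fs)
    r$data[seq_len(k), 801:1000] <- 7  # 0.5 s flat segment
    r
  }
  det8 <- detect_dropout_windows(flat_on(8))
  expect_gt(sum(det8$window_flags), 0)
  # neighbours of flagged windows are flagged too
  core <- which(vapply(det8$window_starts, function(s0) {
    s0 >= 801 && (s0 + 0.1 * fs - 1) <= 1000
  }, logical(1)))
  expect_true(all(det8$window_flags[range(core) + c(-1, 1)]))
  # samples of flagged windows are masked
  expect_true(all(det8$rec$missing_mask[, 850:950]))

  det7 <- detect_dropout_windows(flat_on(7))
  expect_equal(sum(det7$window_flags), 0)

  # flag set is invariant to channel permutation
  rp <- flat_on(8)
  perm <- sample(16)
  rp$data <- rp$data[perm, ]
  expect_identical(detect_dropout_windows(rp)$window_flags, det8$window_flags)

  # adding a non-flat channel does not add flags at fixed channel count
  r17 <- flat_on(8)
  r17 <- seizure_recording(rbind(r17$data, rnorm(2000, sd = 50)), fs)
  det17 <- detect_dropout_windows(r17, min_flat_channels = 8)
  expect_true(all(det17$window_flags[det8$window_flags] |
                    !any(det8$window_flags)))
  expect_equal(sum(det17$window_flags & !det8$window_flags), 0)
})

test_that("short gaps are linearly interpolated, long and edge gaps are not", {
  fs <- 100
  mk <- function(mask_idx, n = 20) {
    m <- matrix(FALSE, 1, n)
    m[1, mask_idx] <- TRUE
    r <- seizure_recording(matrix(as.numeric(0:(n - 1)), 1, byrow = TRUE),
                           fs, missing_mask = m)
    r$data[1, mask_idx] <- -99
    r
  }
  # 2-sample gap (0.02 s < 0.05 s): filled with the linear values
  out <- interpolate_short_gaps(mk(2:3))
  expect_equal(out$data[1, 1:4], c(0, 1, 2, 3))
  expect_false(any(out$missing_mask))
  # 6-sample gap (0.06 s >= 0.05 s): untouched
  long <- interpolate_short_gaps(mk(5:10))
  expect_equal(long$data[1, 5:10], rep(-99, 6))
  expect_true(all(long$missing_mask[1, 5:10]))
  # gap at the recording edge: left missing
  edge <- interpolate_short_gaps(mk(1:2))
  expect_true(all(edge$missing_mask[1, 1:2]))
  # no gaps: identity
  clean <- seizure_recording(matrix(rnorm(20), 1), fs)
  expect_identical(interpolate_short_gaps(clean), clean)
})

test_that("common average referencing conserves and is idempotent", {
  set.seed(4)
  rec <- seizure_recording(matrix(rnorm(5 * 500), 5), 250)
  out <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  expect_equal(common_average_reference(out)$data, out$data,
               tolerance = 1e-12)
  expect_error(common_average_reference(
    seizure_recording(matrix(rnorm(500), 1), 250)), "at least 2")
  # excluded channels do not enter the reference
  rec$excluded_channels <- "ch5"
  out2 <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out2$data[1:4, ]))), 1e-9)
  expect_identical(out2$data[5, ], rec$data[5, ])
})

test_that("zero-phase Butterworth filtering attenuates notches and DC, passes band", {
  fs <- 512
  t <- seq(1 / fs, 12, by = 1 / fs)
  core <- (2 * fs):(10 * fs)
  pow <- function(v) mean(v^2)
  sine <- function(f) matrix(sin(2 * pi * f * t), 1, byrow = TRUE)

  r50 <- filter_recording(seizure_recording(sine(50), fs), notch_freqs = 50)
  expect_lt(pow(r50$data[1, core]) / pow(sine(50)[1, core]), 0.01)

  rdc <- filter_recording(seizure_recording(matrix(5, 1, length(t)), fs),
                          notch_freqs = numeric())
  expect_lt(abs(mean(rdc$data[1, core])), 0.05)

  r10 <- filter_recording(seizure_recording(sine(10), fs), notch_freqs = 50)
  amp_ratio <- sqrt(pow(r10$data[1, core]) / pow(sine(10)[1, core]))
  expect_gt(amp_ratio, 0.9)
  expect_lt(amp_ratio, 1.1)

  expect_error(filter_recording(seizure_recording(sine(10), fs = 200)),
               "sampling rate")
})

test_that("recordings resample to the lowest rate with content preserved", {
  fs_hi <- 1000
  t <- seq(1 / fs_hi, 2, by = 1 / fs_hi)
  r1 <- seizure_recording(matrix(sin(2 * pi * 10 * t), 1, byrow = TRUE), fs_hi)
  r2 <- seizure_recording(matrix(rnorm(1000), 1), 500)
  out <- resample_to_common(list(r1, r2))
  expect_equal(out[[1]]$fs, 500)
  expect_equal(ncol(out[[1]]$data), 1000, tolerance = 1)
  expect_identical(out[[2]], r2)
  rms <- function(v) sqrt(mean(v^2))
  expect_equal(rms(out[[1]]$data[1, 100:900]) / rms(r1$data[1, 200:1800]), 1,
               tolerance = 0.05)
  # equal rates: identity
  same <- resample_to_common(list(r2, r2))
  expect_identical(same[[1]], r2)
})
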