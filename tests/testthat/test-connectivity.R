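test_that("band coherence is 1 for identical signals and bounded in [0,1]", {
  fs <- 256
  set.seed(5)
  x <- rnorm(10 * fs)
  for (b in seq_len(nrow(canonical_bands()) - 1)) {
    expect_equal(band_coherence(x, x, canonical_bands()[b, ], fs), 1,
                 tolerance = 1e-9)
  }
  # bounds over randomized signal pairs (including correlated ones)
  for (r in 1:20) {
    y <- 0.5 * x + rnorm(length(x), sd = runif(1, 0.1, 2))
    C <- band_coherence(x, y, c(8, 13), fs)
    expect_gte(C, 0)
    expect_lte(C, 1)
  }
  expect_error(band_coherence(x, x, c(0.05, 0.2), fs), "no FFT bins")
  expect_error(band_coherence(x, x, c(80, 150), 256), "Nyquist")
})

test_that("coherence of a delayed copy stays near 1 within a band", {
  fs <- 256
  set.seed(6)
  x <- as.numeric(signal::filtfilt(signal::butter(2, c(8, 13) / (fs / 2),
                                                  "pass"), rnorm(12 * fs)))
  x <- x[(fs + 1):(11 * fs)]
  lag <- 5  # ~20 ms, far below the 2 s Welch subwindow
  xd <- c(rep(0, lag), x)[seq_along(x)]
  expect_gt(band_coherence(x, xd, c(8, 13), fs), 0.95)
})

test_that("independent signals fall below the Monte-Carlo null quantile", {
  fs <- 256
  n <- 10 * fs
  null_draws <- vapply(1:300, function(b) {
    set.seed(10000 + b)
    band_coherence(rnorm(n), rnorm(n), c(8, 13), fs)
  }, numeric(1))
  q95 <- as.numeric(quantile(null_draws, 0.95))
  fresh <- vapply(1:20, function(b) {
    set.seed(20000 + b)
    band_coherence(rnorm(n), rnorm(n), c(8, 13), fs)
  }, numeric(1))
  expect_lt(mean(fresh), q95)
})

test_that("fc series windowing, feature count and normalization follow the rules", {
  d <- make_dictionary(16, 2, seed = 8, structure = "rank1")
  pw <- latent_pathway(c(1, 2), c(0.5, 0.5))
  rec <- realize_raw_seizure(d, pw, seizure_spec(1, 30, seed = 3), fs = 400,
                             channel_noise_sd = 0.1)
  fc <- compute_fc_series(rec)
  expect_equal(nrow(fc$features), 21)        # floor(30) - 9
  expect_equal(ncol(fc$features), 720)       # 6 x (16^2-16)/2
  expect_true(all(fc$features >= 0))
  for (b in 1:6) {
    sums <- rowSums(fc$features[, fc$band_index == b])
    expect_equal(sums, rep(1, 21), tolerance = 1e-9)
  }
  short <- seizure_recording(matrix(rnorm(16 * 400 * 8), 16), 400)
  expect_error(compute_fc_series(short), "below the")
})

test_that("channel permutation permutes features consistently", {
  set.seed(9)
  fs <- 400
  n <- 5
  rec <- seizure_recording(matrix(rnorm(n * 12 * fs), n), fs)
  fc <- compute_fc_series(rec)
  perm <- c(3, 1, 5, 2, 4)
  recp <- seizure_recording(rec$data[perm, ], fs)
  fcp <- compute_fc_series(recp)
  # pair (a, b) of the permuted montage is pair (perm[a], perm[b]) of the
  # original; map each permuted feature back to its original position
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  remap <- vapply(seq_len(nrow(pairs)), function(k) {
    ij <- sort(perm[pairs[k, ]])
    which(pairs[, 1] == ij[1] & pairs[, 2] == ij[2])
  }, integer(1))
  n_pairs <- nrow(pairs)
  for (b in 1:2) {
    off <- (b - 1) * n_pairs
    expect_equal(fcp$features[, off + seq_len(n_pairs)],
                 fc$features[, off + remap], tolerance = 1e-9)
  }
})

test_that("missing subwindows are tolerated up to the 5-subwindow rule", {
  set.seed(10)
  fs <- 400
  rec <- seizure_recording(matrix(rnorm(4 * 12 * fs), 4), fs)
  # a 2.5-4.5 s hole touches exactly 4 of the 9 overlapping 2 s subwindows
  # of the first 10 s window ([1,3), [2,4), [3,5), [4,6)): retained
  rec4 <- rec
  rec4$missing_mask[, (2.5 * fs + 1):(4.5 * fs)] <- TRUE
  fc4 <- compute_fc_series(rec4)
  expect_false(fc4$missing_windows[1])
  # a 2-6 s hole touches 5 subwindows: window 1 becomes missing
  rec5 <- rec
  rec5$missing_mask[, (2 * fs + 1):(6 * fs)] <- TRUE
  fc5 <- compute_fc_series(rec5)
  expect_true(fc5$missing_windows[1])
  # tolerance off: any missing subwindow voids the window
  fc0 <- compute_fc_series(rec4, max_missing_subwindows = 0)
  expect_true(fc0$missing_windows[1])
})

test_that("seizures with missing windows are excluded, others retained", {
  co <- make_test_cohort(seed = 4)
  keep <- exclude_incomplete_seizures(co$fc)
  expect_identical(keep$fc, co$fc)
  expect_length(keep$excluded, 0)
  bad <- co$fc
  bad[[2]]$missing_windows[3] <- TRUE
  dropped <- exclude_incomplete_seizures(bad)
  expect_length(dropped$fc, length(co$fc) - 1)
  expect_identical(dropped$excluded, names(co$fc)[2])
})

test_that("window-to-state assignment recovers the latent alternation", {
  d <- make_dictionary(8, 2, seed = 12, structure = "rank1")
  pw <- latent_pathway(c(1, 2, 1, 2), rep(0.25, 4))
  rec <- realize_raw_seizure(d, pw, seizure_spec(1, 40, seed = 5), fs = 512,
                             channel_noise_sd = 0.05)
  fc <- compute_fc_series(rec)
  tmpl <- do.call(rbind, d$states)
  assigned <- apply(fc$features, 1, function(w)
    which.min(colSums(abs(t(tmpl) - w))))
  # ground-truth state at each window centre (windows are 10 s long)
  centre_u <- (fc$window_times + 5) / 40
  truth <- pw$state_sequence[pmin(4, findInterval(
    centre_u, c(0, cumsum(pw$dwell_fractions)), rightmost.closed = TRUE))]
  expect_gt(mean(assigned == truth), 0.8)
})
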