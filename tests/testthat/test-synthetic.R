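test_that("state dictionaries have normalized, distinguishable, reproducible states", {
  d <- make_dictionary(4, 1, seed = 0)
  expect_length(d$states, 1)
  expect_length(d$states[[1]], 6 * 6)  # (4^2-4)/2 pairs x 6 bands
  for (b in 1:6) {
    expect_equal(sum(d$states[[1]][d$band_index == b]), 1, tolerance = 1e-12)
  }

  d5 <- make_dictionary(16, 5, seed = 1)
  expect_length(d5$states[[3]], 6 * 120)
  dists <- dist(do.call(rbind, d5$states), method = "manhattan")
  expect_true(min(dists) >= 2)

  expect_identical(make_dictionary(8, 3, seed = 7),
                   make_dictionary(8, 3, seed = 7))
  # an unattainable margin must fail explicitly (band blocks have L1 norm 1,
  # so cityblock distance is bounded by 12)
  expect_error(make_dictionary(4, 3, seed = 1, margin = 50, max_tries = 3),
               "margin")
})

test_that("latent pathways validate dwell fractions", {
  p <- latent_pathway(c(1, 2), c(0.5, 0.5))
  expect_equal(sum(p$dwell_fractions), 1)
  expect_error(latent_pathway(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(latent_pathway(integer(0)))
  expect_error(seizure_spec(1, 5), "duration")
  expect_error(seizure_spec(1, 30, truncate_fraction = 0), "truncate")
})

test_that("realized series follow the windowing rule and stay normalized", {
  d <- make_dictionary(6, 3, seed = 2)
  pw <- latent_pathway(1:3, c(0.3, 0.4, 0.3))
  s30 <- realize_fc_series(d, pw, seizure_spec(1, 30, noise_sd = 0.05, seed = 4))
  expect_equal(nrow(s30$features), 21)  # floor(30) - 9
  expect_true(all(s30$features >= 0))
  for (b in 1:6) {
    expect_equal(rowSums(s30$features[, d$band_index == b]),
                 rep(1, 21), tolerance = 1e-9)
  }
  expect_error(realize_fc_series(d, pw, seizure_spec(1, 10.2,
                                                     truncate_fraction = 0.5)),
               "windows")
  # determinism under the spec seed
  s30b <- realize_fc_series(d, pw, seizure_spec(1, 30, noise_sd = 0.05, seed = 4))
  expect_identical(s30$features, s30b$features)
})

test_that("truncation keeps the leading fraction of the pathway", {
  d <- make_dictionary(6, 10, seed = 3, margin = 1)
  pw <- latent_pathway(1:10)
  full <- realize_fc_series(d, pw, seizure_spec(1, 100), crossfade_windows = 0)
  part <- realize_fc_series(d, pw, seizure_spec(1, 100, truncate_fraction = 0.4),
                            crossfade_windows = 0)
  expect_equal(attr(part, "duration_s"), 40)
  # which states appear: the prefix covering the first 40% of dwell mass
  tmpl <- do.call(rbind, d$states)
  nearest <- function(f) apply(f$features, 1, function(w)
    which.min(colSums(abs(t(tmpl) - w))))
  expect_setequal(unique(nearest(part)), 1:4)
  expect_setequal(unique(nearest(full)), 1:10)
  # soundness: shorter duration and smaller pathway size than the parent
  expect_lt(attr(part, "duration_s"), attr(full, "duration_s"))
  expect_lt(pathway_size(part), pathway_size(full))
})

test_that("noiseless same-pathway pairs are closer than cross-pathway pairs", {
  for (seed in 1:3) {
    co <- generate_cohort(cohort_config(n_pathways = 2, seizures_per_pathway = 3,
                                        noise_sd = 0),
                          seed = seed)
    D <- pathway_dissimilarity_matrix(co$fc)
    same <- outer(co$truth$pathway_of, co$truth$pathway_of, "==")
    ut <- upper.tri(D)
    expect_lt(max(D[same & ut]), min(D[!same & ut]))
  }
})

test_that("cohorts honour requested structure and are reproducible", {
  co <- generate_cohort(cohort_config(n_pathways = 2, seizures_per_pathway = 5),
                        seed = 11)
  lab <- co$truth$pair_labels
  ut <- upper.tri(lab)
  expect_equal(sum(!is.na(lab[ut])), 45)
  expect_equal(sum(lab[ut] == "unrelated"), 25)

  co4 <- generate_cohort(cohort_config(n_pathways = 4, seizures_per_pathway = 4,
                                       n_elastic = 2, n_truncated = 4,
                                       n_semblant = 2),
                         seed = 5)
  expect_equal(sum(co4$truth$planted$type == "truncated"), 4)
  expect_equal(sum(co4$truth$pair_labels[upper.tri(co4$truth$pair_labels)] ==
                     "truncated"), 4)
  expect_identical(
    generate_cohort(cohort_config(n_elastic = 1), seed = 9)$fc,
    generate_cohort(cohort_config(n_elastic = 1), seed = 9)$fc
  )
  expect_error(generate_cohort(cohort_config(n_pathways = 1, n_semblant = 1)),
               "two pathways")
  expect_error(generate_cohort(cohort_config(n_pathways = 1,
                                             seizures_per_pathway = 2,
                                             n_elastic = 3)),
               "not enough")
})

test_that("bimodal durations separate into two log-duration modes", {
  co <- generate_cohort(
    cohort_config(n_pathways = 2, seizures_per_pathway = 25, bimodal = TRUE,
                  bimodal_sep = 3, bimodal_by_pathway = TRUE),
    seed = 2
  )
  ld <- log(co$durations_s)
  km <- kmeans(ld, 2, nstart = 10)
  within_sd <- sqrt(mean((ld - km$centers[km$cluster])^2))
  gap_between <- abs(diff(sort(km$centers)))
  # dip-style separation: the modes sit well apart relative to their spread
  expect_gt(gap_between / within_sd, 2)
})

test_that("dropout injection flattens signal, updates the mask, and validates", {
  set.seed(1)
  rec <- seizure_recording(matrix(rnorm(16 * 2000), 16), fs = 400)
  expect_identical(inject_dropout(rec, NULL), rec)
  expect_identical(inject_dropout(rec, data.frame()), rec)

  out <- inject_dropout(rec, data.frame(start_s = 1, end_s = 1.5))
  idx <- 401:600
  expect_true(all(apply(out$data[, idx], 1, function(v) diff(range(v))) == 0))
  expect_true(all(out$missing_mask[, idx]))
  expect_false(any(out$missing_mask[, -idx]))

  expect_error(inject_dropout(rec, data.frame(start_s = 4.5, end_s = 6)),
               "out of range")
  expect_error(inject_dropout(rec, data.frame(start_s = c(1, 1.2),
                                              end_s = c(1.5, 1.8))),
               "overlap")
})

test_that("raw realizations carry band-specific coherent sources", {
  d <- make_dictionary(8, 2, seed = 3, structure = "rank1")
  pw <- latent_pathway(c(1, 2), c(0.5, 0.5))
  spec <- seizure_spec(1, 20, seed = 21)
  rec <- realize_raw_seizure(d, pw, spec, fs = 512, channel_noise_sd = 0.05)
  expect_s3_class(rec, "seizure_recording")
  expect_equal(dim(rec$data), c(8, 20 * 512))
  rec2 <- realize_raw_seizure(d, pw, spec, fs = 512, channel_noise_sd = 0.05)
  expect_identical(rec$data, rec2$data)
  expect_error(realize_raw_seizure(d, pw, spec, fs = 250), "Nyquist")

  # two channels driven by one common 10 Hz source: alpha coherence ~ 1
  t <- seq(1 / 512, 10, by = 1 / 512)
  src <- sin(2 * pi * 10 * t)
  expect_gt(band_coherence(src, src + 1e-8 * rnorm(length(t)),
                           c(8, 13), 512), 1 - 1e-6)
})

test_that("cohort serialization round-trips through CSV/JSON", {
  co <- make_test_cohort(seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$durations_s, co$durations_s, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$fc[[2]]$features, co$fc[[2]]$features, tolerance = 1e-12)
  expect_identical(back$truth$pair_labels, co$truth$pair_labels)
})
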