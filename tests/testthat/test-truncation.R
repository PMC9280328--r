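test_that("pathway grouping cuts the UPGMA dendrogram as expected", {
  expect_equal(group_similar_pathways(matrix(0, 4, 4))$groups, rep(1L, 4))
  # two blocks: within 0.2, between 5
  D <- matrix(5, 6, 6)
  D[1:3, 1:3] <- 0.2; D[4:6, 4:6] <- 0.2
  diag(D) <- 0
  g <- group_similar_pathways(D, cut = 1)
  expect_equal(length(unique(g$groups)), 2)
  expect_equal(g$groups[1:3], rep(g$groups[1], 3))
  # centroid: strictly smallest mean dissimilarity wins
  D2 <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.4,
                 0.5, 0.4, 0), 3, 3)
  g2 <- group_similar_pathways(D2, cut = 1)
  expect_equal(unname(g2$centroids), 2L)  # means: .3, .25, .45
})

test_that("pathway size is the maximum pairwise cityblock spread", {
  expect_equal(pathway_size(matrix(runif(5), 1)), 0)
  two <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(pathway_size(two), 3)
  expect_equal(pathway_size(matrix(2, 6, 4)), 0)
  set.seed(40)
  P <- matrix(runif(12), 4, 3)
  expect_equal(pathway_size(P),
               max(as.matrix(dist(P, method = "manhattan"))))
})

test_that("partial dissimilarity profiles equal DTW on sliced prefixes", {
  set.seed(41)
  B <- matrix(runif(6 * 4), 6, 4)
  A <- B[1:3, ]
  prof <- partial_dissimilarity_profile(A, B)
  expect_length(prof, 6)
  expect_equal(prof[3], 0)
  profBB <- partial_dissimilarity_profile(B, B)
  expect_equal(profBB[6], 0)
  # slice-and-compare oracle
  A2 <- matrix(runif(4 * 3), 4, 3)
  B2 <- matrix(runif(5 * 3), 5, 3)
  prof2 <- partial_dissimilarity_profile(A2, B2)
  for (m in 1:5) {
    expect_equal(prof2[m], dtw_dissimilarity(A2, B2[1:m, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("a noiseless prefix seizure is flagged as a truncation pair", {
  d <- make_dictionary(6, 4, seed = 42)
  pw <- latent_pathway(1:4, c(0.5, 0.2, 0.15, 0.15))
  parent <- realize_fc_series(d, pw, seizure_spec(1, 60))
  child <- realize_fc_series(d, pw, seizure_spec(1, 60, truncate_fraction = 0.4))
  paths <- list(a = child, b = parent)
  D <- pathway_dissimilarity_matrix(paths)
  durs <- c(a = attr(child, "duration_s"), b = attr(parent, "duration_s"))
  tr <- find_truncation_pairs(paths, D, durs)
  expect_true(tr$pair_matrix[1, 2])
  expect_false(tr$pair_matrix[2, 1])
  expect_equal(tr$proportion, 1)

  # time-reversed partner is not a truncation
  rev_child <- child
  rev_child$features <- parent$features[rev(seq_len(nrow(parent$features))), ]
  paths_rev <- list(a = rev_child, b = parent)
  Dr <- pathway_dissimilarity_matrix(paths_rev)
  tr_rev <- find_truncation_pairs(paths_rev, Dr, durs)
  expect_false(any(tr_rev$pair_matrix))
})

test_that("truncation detection is antisymmetric and relabelling-invariant", {
  co <- generate_cohort(
    cohort_config(n_pathways = 3, seizures_per_pathway = 2, n_truncated = 2,
                  noise_sd = 0.002),
    seed = 43
  )
  D <- pathway_dissimilarity_matrix(co$fc)
  tr <- find_truncation_pairs(co$fc, D, co$durations_s)
  expect_false(any(tr$pair_matrix & t(tr$pair_matrix)))
  # relabelling invariance of the proportion
  perm <- sample(length(co$fc))
  trp <- find_truncation_pairs(co$fc[perm], D[perm, perm],
                               co$durations_s[perm])
  expect_equal(trp$proportion, tr$proportion)
  # a single group yields no ordered pairs
  same <- matrix(runif(15), 3, 5)
  ones <- list(same, same, same)
  D0 <- pathway_dissimilarity_matrix(ones)
  tr0 <- find_truncation_pairs(ones, D0, c(20, 30, 40))
  expect_equal(tr0$proportion, 0)
})
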