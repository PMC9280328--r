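#' Detect duration populations with k-means and the gap statistic
#'
#' Log-transforms the durations, runs k-means for `k = 1, ...,
#' min(s, k_max)` (10 restarts per k), and selects the number of clusters
#' with the gap statistic: `n_ref` reference datasets drawn uniformly over
#' the observed range of the log durations, standard errors with the
#' `sqrt(1 + 1/n_ref)` small-sample correction, and the firstMaxSE rule —
#' the smallest `k` with `gap(k) >= gap(k+1) - SE(k+1)`. `k = 1` means no
#' evidence of multiple duration populations.
#'
#' @param durations_s positive numeric vector, `s >= 2`.
#' @param k_max maximum number of clusters scanned (default 10).
#' @param n_ref number of reference datasets (default 1000).
#' @param seed integer seed.
#' @return list of class `cluster_partition`: `labels` (1..k per seizure,
#'   ordered so cluster 1 has the smallest mean log duration), `k`,
#'   `source = "duration"`, `gap` (the clusGap table or `NULL`).
#' @export
cluster_durations <- function(durations_s, k_max = 10, n_ref = 1000,
                              seed = NULL) {
  if (any(durations_s <= 0)) stop("durations must be positive")
  s <- length(durations_s)
  if (s < 2) stop("need at least 2 seizures")
  ld <- matrix(log(durations_s), ncol = 1)
  # k = s (all singletons, zero within-SS) is never an informative optimum
  # and Hartigan-Wong k-means requires k < n, so the scan stops at s - 1
  K_max <- min(s - 1, k_max, length(unique(ld)))
  if (K_max < 2) {
    return(structure(list(labels = rep(1L, s), k = 1L, source = "duration",
                          gap = NULL),
                     class = "cluster_partition"))
  }
  km <- function(x, k) kmeans(x, k, nstart = 10, iter.max = 50)
  res <- with_seed(seed, {
    gap <- cluster::clusGap(ld, FUNcluster = km, K.max = K_max, B = n_ref,
                            spaceH0 = "original", verbose = FALSE)
    tab <- gap$Tab
    k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                        method = "Tibs2001SEmax")
    labels <- if (k == 1) rep(1L, s) else km(ld, k)$cluster
    list(k = as.integer(k), labels = labels, tab = tab)
  })
  # stable label order: cluster 1 = shortest durations
  ord <- order(vapply(seq_len(res$k), function(g) mean(ld[res$labels == g]),
                      numeric(1)))
  relab <- match(res$labels, ord)
  structure(list(labels = as.integer(relab), k = res$k, source = "duration",
                 gap = res$tab),
            class = "cluster_partition")
}

#' Cut pathway dissimilarities into k clusters
#'
#' UPGMA hierarchical clustering of the pathway dissimilarity matrix, with
#' the dendrogram cut to produce exactly `k` groups (typically the number of
#' duration populations found by [cluster_durations()]).
#'
#' @param D_path pathway [dissimilarity_matrix()].
#' @param k number of clusters, `1 <= k <= s`.
#' @return a `cluster_partition` with `source = "pathway"`.
#' @export
cluster_pathways <- function(D_path, k) {
  stopifnot(is.matrix(D_path), is_square_symmetric(D_path))
  s <- nrow(D_path)
  if (k > s) stop("k cannot exceed the number of seizures")
  if (k < 1) stop("k must be at least 1")
  labels <- if (s == 1) 1L else {
    hc <- hclust(stats::as.dist(D_path), method = "average")
    as.integer(cutree(hc, k = k))
  }
  structure(list(labels = labels, k = as.integer(k), source = "pathway",
                 gap = NULL),
            class = "cluster_partition")
}

#' Rand index and adjusted Rand index of two partitions
#'
#' Computed from the contingency table of the two labelings. The Rand index
#' is the proportion of element pairs on which the partitions agree; the
#' ARI subtracts its expected value under random label permutation and
#' rescales so that identical partitions score 1 and chance scores ~0.
#'
#' @param labels1,labels2 vectors of cluster labels over the same elements.
#' @return list with `rand_index` and `adjusted_rand_index`.
#' @export
rand_indices <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) stop("mismatched lengths")
  n <- length(labels1)
  if (n < 2) stop("need at least 2 elements")
  tab <- table(labels1, labels2)
  nij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  ri <- (total + 2 * nij - a - b) / total
  expected <- a * b / total
  max_index <- (a + b) / 2
  ari <- if (max_index == expected) {
    # both partitions trivial (all-singletons or all-one-cluster)
    if (nij == expected) 1 else 0
  } else {
    (nij - expected) / (max_index - expected)
  }
  list(rand_index = ri, adjusted_rand_index = ari)
}

#' Permutation test for agreement between two partitions
#'
#' Computes the Rand index and ARI between a duration-based and a
#' pathway-based partition, then permutes the membership of the second
#' partition `n_perm` times to build null distributions; one-sided p-values
#' (null >= observed) use the add-one convention.
#'
#' @param p1,p2 `cluster_partition` objects or plain label vectors over the
#'   same seizures.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `rand_index`, `adjusted_rand_index`, `p_rand`, `p_ari`,
#'   `n_perm`, `seed`.
#' @export
partition_agreement <- function(p1, p2, n_perm = 10000, seed = NULL) {
  l1 <- if (inherits(p1, "cluster_partition")) p1$labels else p1
  l2 <- if (inherits(p2, "cluster_partition")) p2$labels else p2
  if (length(l1) != length(l2)) stop("partitions cover different seizures")
  obs <- rand_indices(l1, l2)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      r <- rand_indices(l1, sample(l2))
      c(r$rand_index, r$adjusted_rand_index)
    }, numeric(2))
  })
  list(
    rand_index = obs$rand_index,
    adjusted_rand_index = obs$adjusted_rand_index,
    p_rand = (sum(perm[1, ] >= obs$rand_index - 1e-12) + 1) / (n_perm + 1),
    p_ari = (sum(perm[2, ] >= obs$adjusted_rand_index - 1e-12) + 1) /
      (n_perm + 1),
    n_perm = n_perm,
    seed = seed
  )
}
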