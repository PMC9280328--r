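#' Group seizures with very similar pathways
#'
#' UPGMA (average-linkage) hierarchical clustering of the pathway
#' dissimilarity matrix, cutting the dendrogram at a fixed dissimilarity
#' (default 1). Merges at heights less than or equal to the cut stay merged.
#' Each group's centroid is the seizure with the lowest mean pathway
#' dissimilarity to the other members; singletons are their own centroid.
#'
#' @param D pathway [dissimilarity_matrix()] (or symmetric matrix).
#' @param cut dendrogram cut height.
#' @return list with `groups` (integer group label per seizure) and
#'   `centroids` (seizure index of each group's representative).
#' @export
group_similar_pathways <- function(D, cut = 1.0) {
  stopifnot(is.matrix(D), is_square_symmetric(D))
  s <- nrow(D)
  if (s == 1) {
    return(list(groups = 1L, centroids = 1L))
  }
  hc <- hclust(stats::as.dist(D), method = "average")
  # inclusive cut: merges at exactly `cut` stay merged
  groups <- cutree(hc, h = cut + 1e-9)
  centroids <- vapply(seq_len(max(groups)), function(g) {
    members <- which(groups == g)
    if (length(members) == 1) return(members)
    means <- rowMeans(D[members, members, drop = FALSE]) *
      length(members) / (length(members) - 1)
    members[which.min(means)]
  }, integer(1))
  list(groups = groups, centroids = centroids)
}

#' Pathway size
#'
#' The spread of one seizure's pathway in functional-network space: the
#' maximum cityblock (L1) distance between any two of its time windows.
#' A single-window pathway has size zero.
#'
#' @param P an [fc_series()] or windows x features matrix.
#' @return non-negative scalar.
#' @export
pathway_size <- function(P) {
  P <- fc_matrix(P)
  m <- nrow(P)
  if (m < 1) stop("empty pathway")
  if (m == 1) return(0)
  max(dist(P, method = "manhattan"))
}

#' Partial pathway dissimilarity profile
#'
#' DTW dissimilarity between pathway `A` and the first `m` windows of
#' pathway `B`, for `m = 1, ..., m_B`. If `A` is (close to) a prefix of `B`
#' the profile dips to (near) zero at the matching `m`.
#'
#' @param A,B [fc_series()] objects or windows x features matrices.
#' @return numeric vector of length `m_B`.
#' @export
partial_dissimilarity_profile <- function(A, B) {
  A <- fc_matrix(A); B <- fc_matrix(B)
  if (ncol(A) != ncol(B)) stop("feature dimensions differ")
  dp <- dtw_core(A, B)
  Dt <- dp$D[-1, -1, drop = FALSE]
  mA <- nrow(A)
  vapply(seq_len(nrow(B)), function(m) {
    Dt[mA, m] / dtw_path_length(Dt, mA, m)
  }, numeric(1))
}

#' Detect truncation pairs
#'
#' A truncation pair is an ordered pair of pathway groups (A, B) in which
#' every seizure of A (i) is shorter in duration and (ii) has a smaller
#' pathway size than every seizure of B, and (iii) A's centroid pathway
#' matches the beginning of B's centroid pathway: scanning the partial
#' pathway dissimilarity over prefixes of B, some prefix comes within
#' `dissim_thresh`. All `|A| * |B|` seizure pairs of a flagged group pair
#' count as truncation pairs; the subject-level summary is the proportion of
#' the `s(s-1)/2` seizure pairs related by a truncation. Criteria (i) and
#' (ii) use strict inequalities between the group extrema, so ties fail.
#'
#' @param pathways list of [fc_series()] objects or matrices, one per
#'   seizure.
#' @param D pathway [dissimilarity_matrix()] over the same seizures.
#' @param durations_s positive numeric vector of seizure durations.
#' @param dissim_thresh partial-dissimilarity threshold (default 1.0).
#' @param cut dendrogram cut for [group_similar_pathways()].
#' @return list with `groups`, `centroids`, `group_pairs` (data frame of
#'   flagged ordered group pairs), `pair_matrix` (s x s logical, `TRUE`
#'   where row seizure is a truncated version of column seizure), and
#'   `proportion`.
#' @export
find_truncation_pairs <- function(pathways, D, durations_s,
                                  dissim_thresh = 1.0, cut = 1.0) {
  s <- length(pathways)
  stopifnot(nrow(D) == s, length(durations_s) == s)
  grp <- group_similar_pathways(D, cut = cut)
  sizes <- vapply(pathways, pathway_size, numeric(1))
  n_groups <- max(grp$groups)
  flagged <- NULL
  pair_matrix <- matrix(FALSE, s, s)
  for (a in seq_len(n_groups)) {
    for (b in seq_len(n_groups)) {
      if (a == b) next
      mem_a <- which(grp$groups == a)
      mem_b <- which(grp$groups == b)
      if (!(max(durations_s[mem_a]) < min(durations_s[mem_b]))) next
      if (!(max(sizes[mem_a]) < min(sizes[mem_b]))) next
      prof <- partial_dissimilarity_profile(
        pathways[[grp$centroids[a]]], pathways[[grp$centroids[b]]]
      )
      if (min(prof) <= dissim_thresh) {
        flagged <- rbind(flagged, c(a, b, min(prof)))
        pair_matrix[mem_a, mem_b] <- TRUE
      }
    }
  }
  n_trunc <- sum(pair_matrix)
  group_pairs <- if (is.null(flagged)) {
    data.frame(group_a = integer(), group_b = integer(),
               min_partial_dissim = numeric())
  } else {
    data.frame(group_a = as.integer(flagged[, 1]),
               group_b = as.integer(flagged[, 2]),
               min_partial_dissim = flagged[, 3])
  }
  list(
    groups = grp$groups,
    centroids = grp$centroids,
    group_pairs = group_pairs,
    pair_matrix = pair_matrix,
    proportion = if (s >= 2) n_trunc / (s * (s - 1) / 2) else 0
  )
}
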