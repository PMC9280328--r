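#' Construct a pairwise dissimilarity matrix
#'
#' Symmetric, zero-diagonal, non-negative seizure-by-seizure matrix holding
#' either pathway dissimilarities or duration differences.
#'
#' @param values symmetric numeric matrix.
#' @param seizure_ids character vector of seizure identifiers (dimnames).
#' @param kind `"pathway"` or `"duration"`.
#' @return the matrix with class `dissim_matrix` and a `kind` attribute.
#' @export
dissimilarity_matrix <- function(values, seizure_ids = NULL,
                                 kind = c("pathway", "duration")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (!is_square_symmetric(values)) stop("dissimilarity matrix must be symmetric")
  if (any(values < 0)) stop("dissimilarities must be non-negative")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  seizure_ids <- seizure_ids %||% rownames(values) %||%
    paste0("sz", seq_len(nrow(values)))
  dimnames(values) <- list(seizure_ids, seizure_ids)
  attr(values, "kind") <- kind
  class(values) <- c("dissim_matrix", class(values))
  values
}

# dynamic programming core: cumulative cost and per-cell aligned-path length
# under unit steps (match / insert / delete), both endpoints anchored.
# Ties in the backtrack prefer the diagonal step, so among equally cheap
# warping paths a shortest one is reported.
dtw_core <- function(P, Q) {
  m1 <- nrow(P); m2 <- nrow(Q)
  # local cost: L1 (cityblock) distance between window feature vectors
  cost <- matrix(0, m1, m2)
  for (i in seq_len(m1)) {
    cost[i, ] <- colSums(abs(t(Q) - P[i, ]))
  }
  D <- matrix(Inf, m1 + 1, m2 + 1)
  D[1, 1] <- 0
  for (i in seq_len(m1)) {
    for (j in seq_len(m2)) {
      D[i + 1, j + 1] <- cost[i, j] + min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  list(cost = cost, D = D)
}

# backtrack the warping path ending at (i, j); returns its length K
dtw_path_length <- function(D, i, j) {
  K <- 1L
  while (i > 1L || j > 1L) {
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      steps <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      pick <- which.min(steps)  # diagonal preferred on ties
      if (pick == 1L) { i <- i - 1L; j <- j - 1L }
      else if (pick == 2L) i <- i - 1L
      else j <- j - 1L
    }
    K <- K + 1L
  }
  K
}

#' Dynamic-time-warping pathway dissimilarity
#'
#' Aligns two connectivity time series with classic DTW (unit steps, both
#' endpoints anchored, no warping-window constraint), minimizing the total
#' L1 distance between matched windows, and returns the average L1 distance
#' along the optimal warping path: total optimal cost divided by the warped
#' length `K` (the number of aligned window pairs). Repeating a window any
#' number of times (a pure elastic stretch) is absorbed at zero cost, so a
#' pathway and any repeat-stretched copy have dissimilarity 0.
#'
#' @param P,Q [fc_series()] objects or plain windows x features matrices
#'   with equal feature dimension and at least one window each.
#' @param details if `TRUE`, also return the total path cost and length.
#' @return the scalar dissimilarity, or (with `details`) a list with
#'   `dissimilarity`, `total_cost` and `path_length`.
#' @export
dtw_dissimilarity <- function(P, Q, details = FALSE) {
  P <- fc_matrix(P); Q <- fc_matrix(Q)
  if (ncol(P) != ncol(Q)) stop("feature dimensions differ")
  if (nrow(P) < 1 || nrow(Q) < 1) stop("empty pathway")
  dp <- dtw_core(P, Q)
  total <- dp$D[nrow(P) + 1, nrow(Q) + 1]
  K <- dtw_path_length(dp$D[-1, -1, drop = FALSE], nrow(P), nrow(Q))
  d <- total / K
  if (details) list(dissimilarity = d, total_cost = total, path_length = K)
  else d
}

#' Pairwise pathway dissimilarity matrix
#'
#' Computes [dtw_dissimilarity()] for every pair of a subject's seizures.
#'
#' @param pathways list of [fc_series()] objects (or matrices), length >= 2,
#'   optionally named with seizure ids.
#' @return a symmetric [dissimilarity_matrix()] of kind `"pathway"`.
#' @export
pathway_dissimilarity_matrix <- function(pathways) {
  stopifnot(is.list(pathways), length(pathways) >= 2)
  mats <- lapply(pathways, fc_matrix)
  if (any(vapply(mats, nrow, 1L) < 1)) stop("empty pathway in cohort")
  s <- length(mats)
  out <- matrix(0, s, s)
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      out[i, j] <- out[j, i] <- dtw_dissimilarity(mats[[i]], mats[[j]])
    }
  }
  dissimilarity_matrix(out, seizure_ids = names(pathways), kind = "pathway")
}

#' Pairwise duration differences
#'
#' The duration difference between seizures `i` and `j` is the absolute
#' difference of their natural-log durations,
#' \deqn{|\ln(l_i) - \ln(l_j)| = |\ln(l_i / l_j)|,}
#' so it depends only on the ratio of the two durations: 20 s vs 40 s and
#' 60 s vs 120 s both give `ln 2`. A threshold of 0.2 on this measure
#' corresponds to an `exp(0.2) = 1.22`-fold increase over the shorter
#' seizure.
#'
#' @param durations_s positive numeric vector of seizure durations in
#'   seconds, optionally named.
#' @return a symmetric [dissimilarity_matrix()] of kind `"duration"`.
#' @export
duration_difference_matrix <- function(durations_s) {
  if (any(durations_s <= 0)) stop("durations must be positive")
  ld <- log(durations_s)
  out <- abs(outer(ld, ld, "-"))
  dissimilarity_matrix(out, seizure_ids = names(durations_s),
                       kind = "duration")
}
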