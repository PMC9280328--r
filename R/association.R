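#' Spearman correlation of two dissimilarity matrices
#'
#' Rank correlation (average-rank ties) between the upper-triangular entries
#' of two aligned `s x s` matrices — the per-subject statistic relating
#' pathway dissimilarity to duration difference.
#'
#' @param D1,D2 symmetric matrices over the same seizures in the same order,
#'   `s >= 3`.
#' @return rho in `[-1, 1]`, or `NA` (with a warning) when either vector of
#'   upper-triangular entries is constant, where the rank correlation is
#'   undefined.
#' @export
spearman_upper <- function(D1, D2) {
  stopifnot(is.matrix(D1), is.matrix(D2), all(dim(D1) == dim(D2)))
  if (nrow(D1) < 3) stop("need at least 3 seizures")
  v1 <- upper_vec(D1); v2 <- upper_vec(D2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("constant dissimilarities: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(v1, v2, method = "spearman")
}

#' Mantel permutation test for distance-matrix association
#'
#' Tests whether the Spearman correlation between the upper triangles of two
#' dissimilarity matrices exceeds chance. The null is built by jointly
#' permuting the rows and columns of `D2` (preserving its internal distance
#' structure) and recomputing the correlation; the one-sided p-value uses
#' the add-one convention `p = (#\{rho_perm >= rho_obs\} + 1) / (n_perm + 1)`,
#' which cannot be zero. When the number of seizures is so small that fewer
#' than `n_perm` distinct permutations exist, the test enumerates all `s!`
#' permutations exactly instead (with a warning).
#'
#' @param D1,D2 symmetric matrices over the same seizures, `s >= 3`.
#' @param n_perm number of random permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return list with `rho`, `p_value`, `n_perm`, `exhaustive`, `seed`.
#' @export
mantel_test <- function(D1, D2, n_perm = 10000, seed = NULL) {
  stopifnot(is.matrix(D1), is.matrix(D2), all(dim(D1) == dim(D2)))
  s <- nrow(D1)
  if (s < 3) stop("need at least 3 seizures")
  pairs <- upper_pairs(s)
  v1 <- upper_vec(D1)
  if (sd(v1) == 0 || sd(upper_vec(D2)) == 0) {
    warning("constant dissimilarities: Mantel test undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n_perm = n_perm,
                exhaustive = FALSE, seed = seed))
  }
  r1 <- rank(v1)
  r1c <- r1 - mean(r1)
  rho_of <- function(v2) {
    r2 <- rank(v2)
    r2c <- r2 - mean(r2)
    sum(r1c * r2c) / sqrt(sum(r1c^2) * sum(r2c^2))
  }
  rho_obs <- rho_of(upper_vec(D2))
  exhaustive <- factorial(s) <= n_perm
  if (exhaustive) {
    warning(sprintf(
      "only %d distinct permutations for s = %d; enumerating exhaustively",
      factorial(s), s))
    perms <- all_permutations(s)
    rho_perm <- apply(perms, 1, function(p) {
      rho_of(D2[cbind(p[pairs[, 1]], p[pairs[, 2]])])
    })
    # identity permutation is among the enumerated set, so p is exact
    p_value <- mean(rho_perm >= rho_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    rho_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        p <- sample.int(s)
        rho_of(D2[cbind(p[pairs[, 1]], p[pairs[, 2]])])
      }, numeric(1))
    })
    p_value <- (sum(rho_perm >= rho_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(rho = rho_obs, p_value = p_value, n_perm = n_used,
       exhaustive = exhaustive, seed = seed)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard BH step-up over the full set of p-values; returns which tests
#' are rejected at level `alpha` together with the adjusted p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `reject` (logical mask) and `p_adjusted`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(list(reject = logical(0), p_adjusted = numeric(0)))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  padj <- p.adjust(p_values, method = "BH")
  list(reject = padj <= alpha, p_adjusted = padj)
}
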