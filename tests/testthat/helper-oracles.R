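# Independent oracles and fixture builders used across the test files.

# Exhaustive DTW oracle: enumerate every admissible warping path (unit
# steps, endpoints anchored) and return the minimum total cost and the
# length of an optimal path. Branch-and-bound pruning on the running total
# is exact because local costs are non-negative. Only usable for tiny
# instances.
dtw_enumerate <- function(P, Q) {
  m1 <- nrow(P); m2 <- nrow(Q)
  cost <- matrix(0, m1, m2)
  for (i in seq_len(m1)) cost[i, ] <- colSums(abs(t(Q) - P[i, ]))
  best <- Inf
  best_lengths <- integer()
  rec <- function(i, j, acc, len) {
    acc <- acc + cost[i, j]
    len <- len + 1L
    if (acc > best + 1e-9) return(invisible())
    if (i == m1 && j == m2) {
      if (acc < best - 1e-9) {
        best <<- acc
        best_lengths <<- len
      } else {
        best_lengths <<- sort(unique(c(best_lengths, len)))
      }
      return(invisible())
    }
    if (i < m1 && j < m2) rec(i + 1L, j + 1L, acc, len)
    if (i < m1) rec(i + 1L, j, acc, len)
    if (j < m2) rec(i, j + 1L, acc, len)
    invisible()
  }
  rec(1L, 1L, 0, 0L)
  list(total = best, lengths = best_lengths)
}

# Spearman rho computed from first principles (average ranks + the Pearson
# product-moment formula on the ranks), independent of stats::cor.
spearman_by_hand <- function(x, y) {
  rk <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    out
  }
  rx <- rk(x); ry <- rk(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Rand / adjusted Rand indices by direct pair enumeration over all element
# pairs, independent of the contingency-table formula.
rand_by_pairs <- function(l1, l2) {
  n <- length(l1)
  same1 <- outer(l1, l1, "==")[upper.tri(diag(n))]
  same2 <- outer(l2, l2, "==")[upper.tri(diag(n))]
  ri <- mean(same1 == same2)
  # ARI via expected agreement of the pair indicators
  a <- sum(same1 & same2)
  e <- sum(same1) * sum(same2) / length(same1)
  m <- (sum(same1) + sum(same2)) / 2
  ari <- if (m == e) ifelse(a == e, 1, 0) else (a - e) / (m - e)
  list(rand_index = ri, adjusted_rand_index = ari)
}

# small deterministic two-pathway test cohort used by several files
make_test_cohort <- function(seed = 1, noise_sd = 0.002, ...) {
  generate_cohort(
    cohort_config(n_pathways = 2, seizures_per_pathway = 4,
                  noise_sd = noise_sd, ...),
    seed = seed
  )
}

upper_of <- function(m) m[upper.tri(m)]
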