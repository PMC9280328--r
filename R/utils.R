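# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched so package functions never clobber user randomness
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), expr)
}

# row/column indices (i < j) of the upper triangle of an s x s matrix,
# in a fixed column-major order used everywhere a matrix is vectorized
upper_pairs <- function(s) {
  which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
}

# upper-triangular entries of a square matrix as a vector (column-major)
upper_vec <- function(m) {
  m[upper.tri(m)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_square_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# all permutations of 1..n as a matrix (n! rows); only used for small n
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- cbind(rep.int(k, nrow(sub)), sub + (sub >= k))
    out[[k]] <- block
  }
  do.call(rbind, out)
}
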