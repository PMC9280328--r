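#' Sammon map of seizure time windows
#'
#' Projects all seizure time windows into `dim` dimensions (2 by default)
#' by minimizing the Sammon stress
#' \deqn{E = \frac{1}{\sum_{i<j} d_{ij}} \sum_{i<j}
#'   \frac{(d_{ij} - \delta_{ij})^2}{d_{ij}}}
#' over the pairwise L1 distances `d_ij` between the windows' connectivity
#' patterns, so windows with more similar connectivity are placed closer
#' together. The optimization starts from a classical-MDS configuration and
#' descends with a monotone (step-halved) iteration, so the stress never
#' increases across accepted iterations. Zero off-diagonal distances
#' (duplicate windows) are floored at a small epsilon, since the stress
#' weights are `1/d_ij`.
#'
#' @param window_distances symmetric non-negative distance matrix over all
#'   windows (e.g. `dist(features, method = "manhattan")` as a matrix).
#' @param dim embedding dimension (default 2).
#' @param seed integer seed (used only to jitter degenerate initial
#'   configurations).
#' @param niter,tol iteration cap and relative stress tolerance.
#' @return list of class `embedding_result`: `coordinates` (windows x dim),
#'   `stress`, `dim`, `seed`.
#' @export
sammon_map <- function(window_distances, dim = 2, seed = NULL,
                       niter = 500, tol = 1e-9) {
  D <- as.matrix(window_distances)
  stopifnot(is_square_symmetric(D), all(D >= 0))
  n <- nrow(D)
  if (n <= dim) stop("need more windows than embedding dimensions")
  off <- D[upper.tri(D)]
  if (all(off == 0)) stop("all distances are zero; nothing to embed")
  eps <- 1e-6 * max(D)
  D[D < eps] <- eps
  diag(D) <- 0
  init <- cmdscale(D, k = dim)
  if (ncol(init) < dim || any(!is.finite(init)) ||
      anyDuplicated(round(init / max(abs(init)), 10))) {
    init2 <- matrix(0, n, dim)
    if (ncol(init) >= 1) init2[, seq_len(ncol(init))] <- init
    jit <- with_seed(seed %||% 0L,
                     matrix(rnorm(n * dim, sd = 1e-4 * max(D)), n, dim))
    init <- init2 + jit
  }
  fit <- MASS::sammon(stats::as.dist(D), y = init, k = dim,
                      niter = niter, tol = tol, trace = FALSE)
  structure(
    list(coordinates = fit$points, stress = fit$stress, dim = dim,
         seed = seed),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d windows in %d-D, stress %.4g\n",
              nrow(x$coordinates), x$dim, x$stress))
  invisible(x)
}
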