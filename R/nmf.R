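# HALS (hierarchical alternating least squares) solver for
# min ||V - W H||_F^2 with W, H >= 0. V is features x windows.
nmf_hals <- function(V, r, n_iter = 300, tol = 1e-8) {
  Fdim <- nrow(V); N <- ncol(V)
  W <- matrix(runif(Fdim * r, 0.1, 1), Fdim, r) * sqrt(mean(V) / r)
  H <- matrix(runif(r * N, 0.1, 1), r, N) * sqrt(mean(V) / r)
  nv <- sum(V^2)
  err_prev <- Inf
  for (it in seq_len(n_iter)) {
    # update W given H
    HHt <- H %*% t(H)
    VHt <- V %*% t(H)
    for (k in seq_len(r)) {
      d <- HHt[k, k]
      if (d <= 0) next
      wk <- W[, k] + (VHt[, k] - W %*% HHt[, k]) / d
      W[, k] <- pmax(wk, 0)
    }
    # guard against dead components
    dead <- colSums(W) == 0
    if (any(dead)) W[, dead] <- matrix(runif(sum(dead) * Fdim, 0, 1e-4),
                                       Fdim, sum(dead))
    # update H given W
    WtW <- t(W) %*% W
    WtV <- t(W) %*% V
    for (k in seq_len(r)) {
      d <- WtW[k, k]
      if (d <= 0) next
      hk <- H[k, ] + (WtV[k, ] - WtW[k, ] %*% H) / d
      H[k, ] <- pmax(hk, 0)
    }
    if (it %% 10 == 0 || it == n_iter) {
      err <- sum((V - W %*% H)^2) / nv
      if (is.finite(err_prev) && abs(err_prev - err) < tol) break
      err_prev <- err
    }
  }
  err <- sqrt(sum((V - W %*% H)^2) / nv)
  list(W = W, H = H, rel_error = err)
}

# reproducibility of two factorizations' bases: columns are matched one-to-
# one by the assignment maximizing total cosine similarity (exact
# permutation enumeration for rank <= 7, greedy above), and the pair is
# scored by the MINIMUM matched cosine. A rank is reproducible only if its
# least reproducible component is: surplus components at overfit ranks
# match poorly and drag this score down, while a mean over components
# washes them out.
basis_match_similarity <- function(W1, W2) {
  r <- ncol(W1)
  norm1 <- sqrt(colSums(W1^2)); norm2 <- sqrt(colSums(W2^2))
  norm1[norm1 == 0] <- 1; norm2[norm2 == 0] <- 1
  S <- crossprod(W1 / rep(norm1, each = nrow(W1)),
                 W2 / rep(norm2, each = nrow(W2)))
  if (r <= 7) {
    perms <- all_permutations(r)
    idx <- cbind(rep(seq_len(r), times = nrow(perms)), as.vector(t(perms)))
    vals <- matrix(S[idx], nrow = nrow(perms), byrow = TRUE)
    min(vals[which.max(rowSums(vals)), ])
  } else {
    matched <- numeric(r)
    Sg <- S
    for (step in seq_len(r)) {
      best <- which(Sg == max(Sg), arr.ind = TRUE)[1, ]
      matched[step] <- Sg[best[1], best[2]]
      Sg[best[1], ] <- -Inf
      Sg[, best[2]] <- -Inf
    }
    min(matched)
  }
}

#' Stability non-negative matrix factorization
#'
#' Extracts recurring functional-connectivity patterns from a subject's
#' concatenated seizure windows and selects the decomposition rank by
#' stability: for each candidate rank, `n_restarts` factorizations are fit
#' from random initializations (HALS solver minimizing the Frobenius
#' reconstruction error) and the rank's stability is the mean, over restart
#' pairs, of the reproducibility of their matched basis vectors (optimal
#' one-to-one cosine matching, scored by the weakest matched component, so
#' one irreproducible surplus component is enough to mark a rank unstable).
#' The selected rank is the largest whose stability reaches
#' `stability_threshold` (0.9 by default); if no rank does, the most stable
#' rank is used, with a warning. The returned model is the restart with the
#' lowest reconstruction error at the selected rank.
#'
#' @param V non-negative features x windows matrix (seizure windows
#'   concatenated column-wise).
#' @param rank_range candidate ranks, a subset of `1:min(dim(V))`.
#' @param n_restarts factorizations per rank (default 10).
#' @param seed integer seed for the restart stream.
#' @param stability_threshold minimum stability for an acceptable rank.
#' @param n_iter HALS iterations per fit.
#' @return list of class `nmf_model`: `W` (F x r), `H` (r x N), `rank`,
#'   `rel_error`, `stability` (named per candidate rank), `seed`.
#' @export
fit_stability_nmf <- function(V, rank_range = 1:6, n_restarts = 10,
                              seed = NULL, stability_threshold = 0.9,
                              n_iter = 300) {
  stopifnot(is.matrix(V))
  if (any(V < 0)) stop("V must be non-negative")
  rank_range <- sort(unique(as.integer(rank_range)))
  if (any(rank_range < 1) || any(rank_range > min(dim(V)))) {
    stop("rank_range must lie in 1..min(dim(V))")
  }
  out <- with_seed(seed, {
    fits <- lapply(rank_range, function(r) {
      lapply(seq_len(n_restarts), function(b) nmf_hals(V, r, n_iter = n_iter))
    })
    names(fits) <- as.character(rank_range)
    fits
  })
  stability <- vapply(out, function(fits_r) {
    r <- ncol(fits_r[[1]]$W)
    if (r == 0 || length(fits_r) < 2) return(1)
    sims <- combn(length(fits_r), 2, function(ij) {
      basis_match_similarity(fits_r[[ij[1]]]$W, fits_r[[ij[2]]]$W)
    })
    mean(sims)
  }, numeric(1))
  ok <- stability >= stability_threshold
  if (any(ok)) {
    sel <- max(rank_range[ok])
  } else {
    sel <- rank_range[which.max(stability)]
    warning(sprintf(
      "no candidate rank reached stability %.2f; using most stable rank %d",
      stability_threshold, sel))
  }
  fits_sel <- out[[as.character(sel)]]
  best <- fits_sel[[which.min(vapply(fits_sel, `[[`, numeric(1),
                                     "rel_error"))]]
  structure(
    list(W = best$W, H = best$H, rank = sel, rel_error = best$rel_error,
         stability = stats::setNames(stability, rank_range), seed = seed),
    class = "nmf_model"
  )
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("<nmf_model> rank %d, relative error %.3g\n",
              x$rank, x$rel_error))
  cat("  stability:",
      paste(sprintf("r%s=%.2f", names(x$stability), x$stability),
            collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct denoised per-seizure connectivity series
#'
#' Forms the low-rank approximation `W %*% H` and splits its columns back
#' into per-seizure connectivity time series; window counts per seizure are
#' unchanged. Reconstructed features are not re-normalized by default.
#'
#' @param model an [fit_stability_nmf()] result.
#' @param fc_list the list of [fc_series()] objects whose windows were
#'   concatenated (in order) into the columns of `V`.
#' @return list of denoised [fc_series()] objects.
#' @export
nmf_reconstruct <- function(model, fc_list) {
  stopifnot(inherits(model, "nmf_model"), is.list(fc_list))
  counts <- vapply(fc_list, function(f) nrow(fc_matrix(f)), integer(1))
  Vhat <- model$W %*% model$H
  if (sum(counts) != ncol(Vhat)) {
    stop("window counts do not match the fitted matrix columns")
  }
  offsets <- cumsum(c(0, counts))
  out <- lapply(seq_along(fc_list), function(i) {
    cols <- (offsets[i] + 1):offsets[i + 1]
    f <- fc_list[[i]]
    feats <- t(Vhat[, cols, drop = FALSE])
    if (inherits(f, "fc_series")) {
      fc_series(feats, n_channels = f$n_channels, bands = f$bands,
                window_times = f$window_times,
                missing_windows = f$missing_windows)
    } else {
      feats
    }
  })
  names(out) <- names(fc_list)
  out
}

#' Concatenate seizures into the NMF input matrix
#'
#' @param fc_list list of [fc_series()] objects (or matrices) with equal
#'   feature dimension.
#' @return features x windows matrix (seizure windows stacked column-wise).
#' @export
fc_concatenate <- function(fc_list) {
  mats <- lapply(fc_list, fc_matrix)
  do.call(cbind, lapply(mats, t))
}
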