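#' Classify seizure pairs into the four-way taxonomy
#'
#' Each of the `s(s-1)/2` seizure pairs is placed in exactly one category by
#' thresholding its pathway dissimilarity (similar iff `<= thr_path`) and
#' duration difference (similar iff `<= thr_dur`):
#'
#' * `similar-similar`: similar pathways, similar durations (concordant);
#' * `elastic`: similar pathways, different durations — the same route run
#'   at a different speed;
#' * `semblant`: different pathways, similar durations;
#' * `different-different`: different pathways, different durations
#'   (concordant).
#'
#' Both thresholds are inclusive on the "similar" side. The defaults
#' (pathway 1.0, duration 0.2, i.e. up to a 1.22-fold duration ratio) are
#' the conventional operating point; see [calibrate_duration_threshold()]
#' for a data-driven alternative.
#'
#' @param D_path,D_dur aligned pathway and duration [dissimilarity_matrix()]
#'   objects, `s >= 2`.
#' @param thr_path pathway-similarity threshold (default 1.0).
#' @param thr_dur duration-similarity threshold (default 0.2).
#' @return list of class `pair_taxonomy`: `category` (s x s character
#'   matrix, `NA` diagonal), `counts`, `proportions`, `thresholds`, `n_pairs`.
#' @export
classify_pairs <- function(D_path, D_dur, thr_path = 1.0, thr_dur = 0.2) {
  stopifnot(is.matrix(D_path), is.matrix(D_dur))
  if (!all(dim(D_path) == dim(D_dur))) stop("mismatched matrices")
  s <- nrow(D_path)
  if (s < 2) stop("need at least 2 seizures")
  sim_path <- D_path <= thr_path
  sim_dur <- D_dur <= thr_dur
  category <- matrix(NA_character_, s, s, dimnames = dimnames(D_path))
  category[sim_path & sim_dur] <- "similar-similar"
  category[sim_path & !sim_dur] <- "elastic"
  category[!sim_path & sim_dur] <- "semblant"
  category[!sim_path & !sim_dur] <- "different-different"
  diag(category) <- NA_character_
  lev <- c("similar-similar", "elastic", "semblant", "different-different")
  counts <- table(factor(category[upper.tri(category)], levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  n_pairs <- s * (s - 1) / 2
  structure(
    list(
      category = category,
      counts = counts,
      proportions = counts / n_pairs,
      thresholds = c(path = thr_path, dur = thr_dur),
      n_pairs = n_pairs
    ),
    class = "pair_taxonomy"
  )
}

#' @export
print.pair_taxonomy <- function(x, ...) {
  cat(sprintf("<pair_taxonomy> %d pairs (thr_path = %g, thr_dur = %g)\n",
              x$n_pairs, x$thresholds["path"], x$thresholds["dur"]))
  for (k in names(x$counts)) {
    cat(sprintf("  %-20s %4d (%.1f%%)\n", k, x$counts[k],
                100 * x$proportions[k]))
  }
  invisible(x)
}

#' Does a subject display a given pair category?
#'
#' @param taxonomy a [classify_pairs()] result.
#' @param category one of `"similar-similar"`, `"elastic"`, `"semblant"`,
#'   `"different-different"`.
#' @return list with `present` (count >= 1) and `count`.
#' @export
subject_has_category <- function(taxonomy, category) {
  stopifnot(inherits(taxonomy, "pair_taxonomy"),
            category %in% names(taxonomy$counts))
  n <- taxonomy$counts[[category]]
  list(present = n >= 1, count = n)
}

#' Calibrate the duration threshold to match pathway-similarity prevalence
#'
#' Optional helper reproducing the balancing procedure used to pick the
#' default thresholds: given a fixed pathway threshold, choose the duration
#' threshold so that the overall proportion of similar-duration pairs
#' (pooled across subjects) equals the proportion of similar-pathway pairs —
#' i.e. the corresponding quantile of the pooled duration differences.
#'
#' @param D_path_list,D_dur_list lists of aligned pathway and duration
#'   matrices, one per subject (single matrices are accepted).
#' @param thr_path fixed pathway threshold.
#' @return list with `thr_dur`, `prop_similar_path`, `thr_path`.
#' @export
calibrate_duration_threshold <- function(D_path_list, D_dur_list,
                                         thr_path = 1.0) {
  if (is.matrix(D_path_list)) D_path_list <- list(D_path_list)
  if (is.matrix(D_dur_list)) D_dur_list <- list(D_dur_list)
  vp <- unlist(lapply(D_path_list, upper_vec))
  vd <- unlist(lapply(D_dur_list, upper_vec))
  prop <- mean(vp <= thr_path)
  thr_dur <- as.numeric(stats::quantile(vd, probs = prop, type = 1))
  list(thr_dur = thr_dur, prop_similar_path = prop, thr_path = thr_path)
}
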