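#' Write / read a dissimilarity matrix as CSV
#'
#' Matrices are stored with a header row and a leading column of seizure
#' ids. On read the matrix must be square, symmetric (to 1e-8), zero
#' diagonal and non-negative, or the file is rejected.
#'
#' @param D a [dissimilarity_matrix()] (or symmetric matrix).
#' @param path file path.
#' @return `path` invisibly / the matrix.
#' @export
write_dissimilarity_csv <- function(D, path) {
  stopifnot(is.matrix(D))
  ids <- rownames(D) %||% paste0("sz", seq_len(nrow(D)))
  m <- unclass(D)
  attr(m, "kind") <- NULL
  df <- data.frame(seizure_id = ids, m, check.names = FALSE)
  colnames(df) <- c("seizure_id", ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity_csv
#' @param kind expected matrix kind on read.
#' @export
read_dissimilarity_csv <- function(path, kind = c("pathway", "duration")) {
  kind <- match.arg(kind)
  df <- read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!is_square_symmetric(m)) stop("matrix in ", path, " is not symmetric")
  dimnames(m) <- list(ids, ids)
  dissimilarity_matrix(m, seizure_ids = ids, kind = kind)
}

#' Write / read seizure durations as CSV
#'
#' Two columns, `seizure_id` and `duration_s`. Non-positive durations are
#' rejected on read (the log transform requires > 0).
#'
#' @param durations_s named numeric vector of durations in seconds.
#' @param path file path.
#' @export
write_durations_csv <- function(durations_s, path) {
  ids <- names(durations_s) %||% paste0("sz", seq_along(durations_s))
  write.csv(data.frame(seizure_id = ids, duration_s = as.numeric(durations_s)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_durations_csv
#' @export
read_durations_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("seizure_id", "duration_s") %in% names(df)))
  if (any(df$duration_s <= 0)) {
    stop("non-positive duration in ", path, " (log transform requires > 0)")
  }
  stats::setNames(df$duration_s, df$seizure_id)
}

#' Pipeline configuration
#'
#' Parameters for [run_pipeline()], defaulting to the standard analysis
#' values: 10 s / 9 s-overlap connectivity windows over the six canonical
#' bands, pathway-similarity threshold 1.0, duration-difference threshold
#' 0.2, 10000 permutations for the Mantel and partition-agreement tests,
#' gap statistic with 1000 reference distributions and at most 10 clusters.
#'
#' @param thr_path,thr_dur taxonomy thresholds.
#' @param n_perm permutations for Mantel and partition tests.
#' @param k_max,n_ref duration-population clustering parameters.
#' @param nmf if `TRUE`, denoise the concatenated windows with stability
#'   NMF before the pairwise stages; `FALSE` runs on the raw features.
#' @param nmf_rank_range,nmf_restarts stability-NMF settings.
#' @param embed if `TRUE`, compute the Sammon map of all windows.
#' @param seed master seed for all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(thr_path = 1.0, thr_dur = 0.2, n_perm = 10000,
                            k_max = 10, n_ref = 1000, nmf = FALSE,
                            nmf_rank_range = 1:6, nmf_restarts = 10,
                            embed = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pathway-versus-duration analysis for one subject
#'
#' Orchestrates every stage on a set of connectivity time series and
#' durations: optional stability-NMF denoising, the pathway dissimilarity
#' and duration difference matrices, the Spearman/Mantel association,
#' truncation-pair detection, the four-way pair taxonomy, duration
#' populations (gap statistic) with pathway-cluster agreement, and the
#' Sammon embedding. Results are returned and, if `out_dir` is given,
#' written as CSV/JSON with a run log.
#'
#' @param fc_list named list of [fc_series()] objects (complete, no missing
#'   windows; see [exclude_incomplete_seizures()]).
#' @param durations_s named positive durations, aligned with `fc_list`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `seizpath_results` with components `D_path`,
#'   `D_dur`, `association`, `truncation`, `taxonomy`, `populations`,
#'   `embedding`, `nmf`, `excluded`, `config`.
#' @export
run_pipeline <- function(fc_list, durations_s, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(fc_list) != length(durations_s)) {
    stop("fc_list and durations_s must cover the same seizures")
  }
  if (any(durations_s <= 0)) stop("durations must be positive")
  excl <- exclude_incomplete_seizures(fc_list)
  fc_list <- excl$fc
  if (length(excl$excluded)) {
    durations_s <- durations_s[setdiff(names(durations_s), excl$excluded)]
  }
  if (length(fc_list) < 3) stop("need at least 3 complete seizures")
  nmf_model <- NULL
  if (isTRUE(config$nmf)) {
    V <- fc_concatenate(fc_list)
    nmf_model <- fit_stability_nmf(V, rank_range = config$nmf_rank_range,
                                   n_restarts = config$nmf_restarts,
                                   seed = config$seed)
    fc_list <- nmf_reconstruct(nmf_model, fc_list)
  }
  D_path <- pathway_dissimilarity_matrix(fc_list)
  D_dur <- duration_difference_matrix(durations_s)
  assoc <- mantel_test(D_path, D_dur, n_perm = config$n_perm,
                       seed = config$seed)
  trunc <- find_truncation_pairs(fc_list, D_path, durations_s,
                                 dissim_thresh = config$thr_path,
                                 cut = config$thr_path)
  taxonomy <- classify_pairs(D_path, D_dur, thr_path = config$thr_path,
                             thr_dur = config$thr_dur)
  dur_part <- cluster_durations(durations_s, k_max = config$k_max,
                                n_ref = config$n_ref, seed = config$seed)
  populations <- list(duration = dur_part, pathway = NULL, agreement = NULL)
  if (dur_part$k >= 2) {
    path_part <- cluster_pathways(D_path, k = dur_part$k)
    populations$pathway <- path_part
    populations$agreement <- partition_agreement(
      dur_part, path_part, n_perm = config$n_perm, seed = config$seed)
  }
  embedding <- NULL
  if (isTRUE(config$embed)) {
    allw <- do.call(rbind, lapply(fc_list, fc_matrix))
    embedding <- sammon_map(as.matrix(dist(allw, method = "manhattan")),
                            seed = config$seed)
    embedding$seizure_id <- rep(names(fc_list),
                                vapply(fc_list, function(f)
                                  nrow(fc_matrix(f)), integer(1)))
  }
  res <- structure(
    list(D_path = D_path, D_dur = D_dur, association = assoc,
         truncation = trunc, taxonomy = taxonomy, populations = populations,
         embedding = embedding, nmf = nmf_model, excluded = excl$excluded,
         config = config),
    class = "seizpath_results"
  )
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.seizpath_results <- function(x, ...) {
  s <- nrow(x$D_path)
  cat(sprintf("<seizpath_results> %d seizures, %d pairs\n", s, s * (s - 1) / 2))
  cat(sprintf("  pathway-duration association: rho = %.3f, Mantel p = %.4g\n",
              x$association$rho, x$association$p_value))
  cat(sprintf("  truncation-pair proportion: %.3f\n", x$truncation$proportion))
  cat(sprintf("  duration populations: k = %d\n", x$populations$duration$k))
  if (!is.null(x$populations$agreement)) {
    cat(sprintf("  pathway-cluster agreement: ARI = %.3f (p = %.4g)\n",
                x$populations$agreement$adjusted_rand_index,
                x$populations$agreement$p_ari))
  }
  print(x$taxonomy)
  invisible(x)
}

# write all pipeline artifacts + a small run log
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dissimilarity_csv(res$D_path,
                          file.path(out_dir, "pathway_dissimilarity.csv"))
  write_dissimilarity_csv(res$D_dur,
                          file.path(out_dir, "duration_difference.csv"))
  jfile <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, na = "null",
    force = TRUE)
  jfile(res$association, "association.json")
  jfile(list(groups = res$truncation$groups,
             centroids = res$truncation$centroids,
             group_pairs = res$truncation$group_pairs,
             proportion = res$truncation$proportion), "truncation.json")
  jfile(list(counts = as.list(res$taxonomy$counts),
             proportions = as.list(res$taxonomy$proportions),
             thresholds = as.list(res$taxonomy$thresholds)),
        "taxonomy.json")
  jfile(list(
    k = res$populations$duration$k,
    duration_labels = res$populations$duration$labels,
    pathway_labels = res$populations$pathway$labels,
    agreement = res$populations$agreement), "duration_populations.json")
  if (!is.null(res$embedding)) {
    write.csv(data.frame(seizure_id = res$embedding$seizure_id,
                         res$embedding$coordinates),
              file.path(out_dir, "embedding.csv"), row.names = FALSE)
  }
  jfile(list(
    package_version = as.character(utils::packageVersion("seizpath")),
    r_version = R.version.string,
    seed = res$config$seed,
    nmf = isTRUE(res$config$nmf),
    nmf_rank = res$nmf$rank,
    excluded_seizures = res$excluded,
    timestamp = format(Sys.time(), tz = "UTC")), "run_log.json")
  invisible(out_dir)
}
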