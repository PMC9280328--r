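#' Configuration for a synthetic seizure cohort
#'
#' Defaults describe a small, realistic focal-epilepsy cohort: a few
#' distinct latent pathways per subject, lognormal durations centred on
#' 60 s with log-sd 0.5 (optionally a bimodal lognormal mixture), and
#' requested numbers of planted elastic, truncation and semblant pairs.
#' Each planted pair claims dedicated seizures, so the truth labels are
#' fixed by construction before anything is measured.
#'
#' @param n_pathways number of distinct latent pathways.
#' @param seizures_per_pathway seizures realized per pathway.
#' @param n_channels channels for the connectivity templates.
#' @param states_per_pathway latent states per pathway (pathways use
#'   disjoint state subsets, so different pathways are far apart in
#'   connectivity space).
#' @param segments_per_pathway length of each pathway's state sequence.
#' @param n_elastic,n_truncated,n_semblant requested planted pair counts.
#' @param duration_meanlog,duration_sdlog lognormal duration parameters
#'   (defaults `log(60)` and 0.5).
#' @param bimodal if `TRUE`, durations come from a two-component lognormal
#'   mixture with log-means `bimodal_sep` log-sds apart.
#' @param bimodal_sep separation of the two log-modes in units of
#'   `duration_sdlog` (default 3).
#' @param bimodal_by_pathway if `TRUE`, the mixture component is tied to the
#'   pathway (odd pathways short, even pathways long), giving a ground-truth
#'   correspondence between duration populations and pathway clusters.
#' @param noise_sd feature noise of each realized seizure.
#' @param elastic_log_ratio planted log-duration ratio of elastic pairs
#'   (default 0.7, about a two-fold duration difference).
#' @param truncate_fraction prefix fraction of planted truncated seizures.
#' @param crossfade_windows state cross-fade width in windows.
#' @param margin dictionary distinguishability margin.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_pathways = 2, seizures_per_pathway = 5,
                          n_channels = 8, states_per_pathway = 3,
                          segments_per_pathway = 4,
                          n_elastic = 0, n_truncated = 0, n_semblant = 0,
                          duration_meanlog = log(60), duration_sdlog = 0.5,
                          bimodal = FALSE, bimodal_sep = 3,
                          bimodal_by_pathway = FALSE,
                          noise_sd = 0, elastic_log_ratio = 0.7,
                          truncate_fraction = 0.4, crossfade_windows = 1,
                          margin = 2) {
  cfg <- as.list(environment())
  stopifnot(n_pathways >= 1, seizures_per_pathway >= 1, n_channels >= 2,
            n_elastic >= 0, n_truncated >= 0, n_semblant >= 0,
            duration_sdlog > 0, truncate_fraction > 0, truncate_fraction <= 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic seizure cohort with ground truth
#'
#' Builds a dictionary of latent states, one latent pathway per requested
#' pathway (over disjoint state subsets), draws durations from the
#' configured model, plants the requested elastic / truncation / semblant
#' pairs by claiming dedicated seizures, and realizes every seizure's
#' connectivity time series. Pair truth labels are defined for all
#' `s(s-1)/2` pairs:
#'
#' * `elastic` — planted same-pathway pair with log-duration ratio
#'   `elastic_log_ratio` (> the 0.2 similarity threshold);
#' * `truncated` — planted pair where one seizure realizes only the leading
#'   `truncate_fraction` of its partner's pathway at proportionally shorter
#'   duration;
#' * `semblant` — planted cross-pathway pair with identical durations;
#' * `same-pathway` / `unrelated` — all remaining within- / cross-pathway
#'   pairs.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed; the whole cohort is reproducible from
#'   `config` + `seed`.
#' @return list of class `synthetic_cohort` with `fc` (named list of
#'   [fc_series()]), `durations_s`, `truth` (`pair_labels` s x s matrix,
#'   `pathway_of`, `planted` data frame, `truncation_parents`),
#'   `dictionary`, `pathways`, `specs`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n_pw <- cfg$n_pathways
  spp <- cfg$seizures_per_pathway
  if (cfg$n_semblant > 0 && n_pw < 2) {
    stop("semblant pairs require at least two pathways")
  }
  # feasibility of the requested pair structure
  slots <- rep(spp, n_pw)
  need_two <- cfg$n_elastic + cfg$n_truncated
  avail_two <- sum(pmax(slots, 0) %/% 2)
  if (need_two > sum(slots %/% 2) ||
      2 * need_two + cfg$n_semblant * 2 > sum(slots)) {
    stop("not enough seizures for the requested planted pairs")
  }
  with_seed(seed, {
    n_states <- n_pw * cfg$states_per_pathway
    dict <- make_dictionary(cfg$n_channels, n_states, seed = NULL,
                            margin = cfg$margin)
    pathways <- lapply(seq_len(n_pw), function(p) {
      pool <- ((p - 1) * cfg$states_per_pathway + 1):(p * cfg$states_per_pathway)
      seqn <- integer(cfg$segments_per_pathway)
      for (j in seq_len(cfg$segments_per_pathway)) {
        cand <- if (j == 1) pool else setdiff(pool, seqn[j - 1])
        seqn[j] <- if (length(cand) == 1) cand else sample(cand, 1)
      }
      dw <- rgamma(cfg$segments_per_pathway, shape = 5)
      latent_pathway(seqn, dw / sum(dw))
    })
    s <- n_pw * spp
    pathway_of <- rep(seq_len(n_pw), each = spp)
    # durations
    comp <- if (cfg$bimodal) {
      if (cfg$bimodal_by_pathway) (pathway_of - 1) %% 2 else
        sample(0:1, s, replace = TRUE)
    } else rep(0L, s)
    ml <- cfg$duration_meanlog + comp * cfg$bimodal_sep * cfg$duration_sdlog
    durations <- rlnorm(s, meanlog = ml, sdlog = cfg$duration_sdlog)
    durations <- pmax(durations, 10.5)
    warp <- rep(1, s)
    trunc <- rep(1, s)
    claimed <- rep(FALSE, s)
    planted <- data.frame(type = character(), i = integer(), j = integer())
    claim_two_same <- function() {
      free_by_pw <- vapply(seq_len(n_pw),
                           function(p) sum(!claimed & pathway_of == p),
                           numeric(1))
      p <- which.max(free_by_pw)
      if (free_by_pw[p] < 2) stop("not enough free seizures on one pathway")
      which(!claimed & pathway_of == p)[1:2]
    }
    for (e in seq_len(cfg$n_elastic)) {
      ij <- claim_two_same()
      claimed[ij] <- TRUE
      durations[ij[2]] <- durations[ij[1]] * exp(cfg$elastic_log_ratio)
      warp[ij[2]] <- 1.25
      planted <- rbind(planted, data.frame(type = "elastic",
                                           i = ij[1], j = ij[2]))
    }
    for (tr in seq_len(cfg$n_truncated)) {
      ij <- claim_two_same()
      claimed[ij] <- TRUE
      # ij[1] becomes a prefix child of ij[2]. The prefix is capped inside
      # the parent pathway's first dwell segment so the child's pathway size
      # is strictly smaller than the parent's (a prefix spanning several
      # states can tie the parent's diameter exactly, which the strict
      # truncation criteria reject).
      p <- pathway_of[ij[1]]
      tf <- min(cfg$truncate_fraction, 0.7 * pathways[[p]]$dwell_fractions[1])
      durations[ij[2]] <- max(durations[ij[2]], 12 / tf)
      durations[ij[1]] <- durations[ij[2]]
      trunc[ij[1]] <- tf
      planted <- rbind(planted, data.frame(type = "truncated",
                                           i = ij[1], j = ij[2]))
    }
    for (sm in seq_len(cfg$n_semblant)) {
      free_by_pw <- vapply(seq_len(n_pw),
                           function(p) sum(!claimed & pathway_of == p),
                           numeric(1))
      ps <- order(free_by_pw, decreasing = TRUE)[1:2]
      if (any(free_by_pw[ps] < 1)) {
        stop("not enough free seizures on two pathways for a semblant pair")
      }
      i <- which(!claimed & pathway_of == ps[1])[1]
      j <- which(!claimed & pathway_of == ps[2])[1]
      claimed[c(i, j)] <- TRUE
      durations[j] <- durations[i]
      planted <- rbind(planted, data.frame(type = "semblant", i = i, j = j))
    }
    seeds <- sample.int(.Machine$integer.max - 1L, s)
    specs <- lapply(seq_len(s), function(i) {
      seizure_spec(pathway_of[i], durations[i], warp = warp[i],
                   truncate_fraction = trunc[i], noise_sd = cfg$noise_sd,
                   seed = seeds[i])
    })
    fc <- lapply(specs, function(sp) {
      realize_fc_series(dict, pathways[[sp$pathway_id]], sp,
                        crossfade_windows = cfg$crossfade_windows)
    })
    ids <- sprintf("sz%03d", seq_len(s))
    names(fc) <- ids
    realized <- vapply(fc, function(f) attr(f, "duration_s"), numeric(1))
    names(realized) <- ids
    # truth labels for every pair
    labels <- matrix(NA_character_, s, s, dimnames = list(ids, ids))
    same <- outer(pathway_of, pathway_of, "==")
    labels[same] <- "same-pathway"
    labels[!same] <- "unrelated"
    diag(labels) <- NA_character_
    for (r in seq_len(nrow(planted))) {
      i <- planted$i[r]; j <- planted$j[r]
      labels[i, j] <- labels[j, i] <- planted$type[r]
    }
    trunc_parents <- planted[planted$type == "truncated",
                             c("i", "j"), drop = FALSE]
    names(trunc_parents) <- c("child", "parent")
    structure(
      list(
        fc = fc,
        durations_s = realized,
        truth = list(pair_labels = labels, pathway_of = pathway_of,
                     planted = planted, truncation_parents = trunc_parents),
        dictionary = dict,
        pathways = pathways,
        specs = specs,
        config = cfg,
        seed = seed
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d seizures on %d pathways (seed %s)\n",
    length(x$fc), x$config$n_pathways, format(x$seed)))
  if (nrow(x$truth$planted)) {
    tb <- table(x$truth$planted$type)
    cat("  planted pairs:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' Serialize a synthetic cohort to a directory
#'
#' Writes `cohort.json` (config, seed, truth labels), one
#' `fc_XXXX.csv` per seizure (windows x features) and `durations.csv`
#' (`seizure_id,duration_s`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$fc)
  meta <- list(
    config = cohort$config[setdiff(names(cohort$config), "")],
    seed = cohort$seed,
    seizure_ids = ids,
    n_channels = cohort$dictionary$n_channels,
    pathway_of = cohort$truth$pathway_of,
    pair_labels = cohort$truth$pair_labels,
    planted = cohort$truth$planted
  )
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  for (i in seq_along(ids)) {
    write.csv(cohort$fc[[i]]$features,
              file.path(dir, sprintf("fc_%04d.csv", i)), row.names = FALSE)
  }
  write_durations_csv(cohort$durations_s, file.path(dir, "durations.csv"))
  invisible(dir)
}

#' Read a serialized cohort directory
#'
#' @param dir directory written by [write_cohort()].
#' @return list with `fc` (named list of [fc_series()]), `durations_s`,
#'   `truth` and `meta` (the parsed `cohort.json`).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  ids <- meta$seizure_ids
  fc <- lapply(seq_along(ids), function(i) {
    feats <- as.matrix(read.csv(file.path(dir, sprintf("fc_%04d.csv", i))))
    dimnames(feats) <- NULL
    fc_series(feats, n_channels = meta$n_channels)
  })
  names(fc) <- ids
  durations <- read_durations_csv(file.path(dir, "durations.csv"))
  labels <- meta$pair_labels
  if (!is.null(labels)) dimnames(labels) <- list(ids, ids)
  list(fc = fc, durations_s = durations,
       truth = list(pair_labels = labels, pathway_of = meta$pathway_of,
                    planted = meta$planted),
       meta = meta)
}
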