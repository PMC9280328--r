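# Synthetic seizure cohorts with known latent pathway structure.
#
# A seizure is modelled as a trajectory through a small dictionary of latent
# network states; each state is a band-specific connectivity template (the
# same 6 x (n^2 - n)/2 feature layout produced by compute_fc_series). A
# latent pathway is an ordered state sequence with dwell fractions; a
# seizure realizes the pathway at some duration, optionally time-warped,
# truncated to a prefix, and perturbed with non-negative noise. Because the
# pathway, warp and pair structure are known, every downstream measure
# (DTW dissimilarity, truncation detection, taxonomy, duration populations)
# can be validated against ground truth.

#' Generate a dictionary of latent network states
#'
#' Each state is a band-specific connectivity template: 6 band blocks of
#' `(n^2 - n)/2` non-negative entries, each block L1-normalized. States are
#' drawn sparsely (so they are mutually distinguishable) and the dictionary
#' is rejected and redrawn until every pair of states is at least `margin`
#' apart in cityblock distance; an impossible margin fails explicitly after
#' `max_tries` redraws.
#'
#' @param n_channels number of channels `n >= 2`.
#' @param n_states number of states `K >= 1`.
#' @param seed integer seed; identical seeds give identical dictionaries.
#' @param margin minimum pairwise cityblock distance between states.
#' @param structure `"random"` (independent sparse edge weights) or
#'   `"rank1"` (templates proportional to an outer product of per-channel
#'   weights, so a raw-signal realization with shared band-limited sources
#'   can reproduce them; see [realize_raw_seizure()]).
#' @param max_tries redraw budget before giving up.
#' @return list of class `state_dictionary` with `states` (list of feature
#'   vectors), `n_channels`, `band_index`, `bands`, `structure`.
#' @export
make_dictionary <- function(n_channels, n_states, seed = NULL, margin = 2,
                            structure = c("random", "rank1"),
                            max_tries = 50) {
  structure_kind <- match.arg(structure)
  stopifnot(n_channels >= 2, n_states >= 1)
  n_pairs <- n_channels * (n_channels - 1) / 2
  bands <- canonical_bands()
  n_bands <- nrow(bands)
  band_index <- rep(seq_len(n_bands), each = n_pairs)
  ut <- upper.tri(matrix(0, n_channels, n_channels))
  draw_state <- function() {
    v <- numeric(n_bands * n_pairs)
    for (b in seq_len(n_bands)) {
      block <- if (structure_kind == "random") {
        rgamma(n_pairs, shape = 0.3, rate = 1)
      } else {
        a <- rgamma(n_channels, shape = 0.5, rate = 1)
        outer(a, a)[ut]
      }
      s <- sum(block)
      if (s <= 0) block[sample.int(n_pairs, 1)] <- 1 else block <- block / s
      v[((b - 1) * n_pairs + 1):(b * n_pairs)] <- block / max(sum(block), 1)
    }
    v
  }
  dict <- with_seed(seed, {
    ok <- NULL
    for (try in seq_len(max_tries)) {
      states <- replicate(n_states, draw_state(), simplify = FALSE)
      dmin <- if (n_states == 1) Inf else
        min(dist(do.call(rbind, states), method = "manhattan"))
      if (dmin >= margin) { ok <- states; break }
    }
    if (is.null(ok)) {
      stop(sprintf(
        "could not draw %d states at pairwise cityblock margin %g in %d tries",
        n_states, margin, max_tries))
    }
    ok
  })
  structure(
    list(states = dict, n_channels = n_channels, band_index = band_index,
         bands = bands, structure = structure_kind),
    class = "state_dictionary"
  )
}

#' Define a latent seizure pathway
#'
#' @param state_sequence ordered vector of state ids (indices into a
#'   dictionary), at least one segment.
#' @param dwell_fractions positive per-segment weights summing to 1;
#'   defaults to equal dwell.
#' @return list of class `latent_pathway`.
#' @export
latent_pathway <- function(state_sequence,
                           dwell_fractions = NULL) {
  stopifnot(length(state_sequence) >= 1)
  J <- length(state_sequence)
  dwell_fractions <- dwell_fractions %||% rep(1 / J, J)
  stopifnot(length(dwell_fractions) == J, all(dwell_fractions > 0))
  if (abs(sum(dwell_fractions) - 1) > 1e-9) {
    stop("dwell_fractions must sum to 1")
  }
  structure(
    list(state_sequence = as.integer(state_sequence),
         dwell_fractions = dwell_fractions),
    class = "latent_pathway"
  )
}

#' Specify one synthetic seizure
#'
#' @param pathway_id index of the latent pathway the seizure follows.
#' @param duration_s nominal full-pathway duration in seconds (>= 10).
#' @param warp monotone dwell-rescaling exponent: pathway position is
#'   traversed as `u^warp`, so `warp != 1` spends relatively longer in early
#'   (`warp > 1`) or late (`warp < 1`) states without changing the route.
#' @param truncate_fraction in `(0, 1]`; values below 1 keep only the
#'   leading fraction of the pathway's dwell mass AND shorten the realized
#'   duration proportionally (realized duration =
#'   `duration_s * truncate_fraction`).
#' @param noise_sd standard deviation of the additive feature noise.
#' @param seed integer seed for this seizure's noise.
#' @return list of class `seizure_spec`.
#' @export
seizure_spec <- function(pathway_id, duration_s, warp = 1,
                         truncate_fraction = 1, noise_sd = 0, seed = NULL) {
  stopifnot(duration_s >= 10, warp > 0,
            truncate_fraction > 0, truncate_fraction <= 1, noise_sd >= 0)
  structure(
    list(pathway_id = as.integer(pathway_id), duration_s = duration_s,
         warp = warp, truncate_fraction = truncate_fraction,
         noise_sd = noise_sd, seed = seed),
    class = "seizure_spec"
  )
}

# template (feature vector) of a pathway at positions u in [0, 1], with a
# linear cross-fade of width `fade_u` (in pathway position) across internal
# segment boundaries
pathway_templates_at <- function(dict, pathway, u, fade_u = 0) {
  bounds <- cumsum(pathway$dwell_fractions)
  J <- length(bounds)
  states <- lapply(pathway$state_sequence, function(k) dict$states[[k]])
  seg_of <- function(x) min(J, findInterval(x, c(0, bounds),
                                            rightmost.closed = TRUE))
  t(vapply(u, function(x) {
    j <- seg_of(x)
    tmpl <- states[[j]]
    if (fade_u > 0) {
      # blend across the nearest internal boundary if within the fade zone
      if (j < J && bounds[j] - x < fade_u / 2) {
        alpha <- (x - (bounds[j] - fade_u / 2)) / fade_u
        tmpl <- (1 - alpha) * tmpl + alpha * states[[j + 1]]
      } else if (j > 1 && x - bounds[j - 1] < fade_u / 2) {
        alpha <- (x - (bounds[j - 1] - fade_u / 2)) / fade_u
        tmpl <- (1 - alpha) * states[[j - 1]] + alpha * tmpl
      }
    }
    tmpl
  }, numeric(length(dict$states[[1]]))))
}

#' Realize a seizure's connectivity time series from its latent pathway
#'
#' The realized duration is `duration_s * truncate_fraction` and yields
#' `m = floor(realized duration) - 9` windows (the same windowing rule as
#' [compute_fc_series()] with its defaults). Window `t` samples the pathway
#' at position `truncate_fraction * g((t - 1/2)/m)` with the monotone warp
#' `g(u) = u^warp`, i.e. a truncated seizure runs the leading prefix of the
#' pathway. Each window is the (cross-faded) state template plus truncated
#' non-negative noise, re-normalized per band.
#'
#' @param dict a [make_dictionary()] result.
#' @param pathway a [latent_pathway()].
#' @param spec a [seizure_spec()].
#' @param crossfade_windows width of the linear cross-fade between adjacent
#'   states, in windows (default 1); 0 for hard switching.
#' @return an [fc_series()] with attribute `duration_s` (realized duration).
#' @export
realize_fc_series <- function(dict, pathway, spec, crossfade_windows = 1) {
  stopifnot(inherits(dict, "state_dictionary"),
            inherits(pathway, "latent_pathway"),
            inherits(spec, "seizure_spec"))
  stopifnot(all(pathway$state_sequence <= length(dict$states)))
  dur <- spec$duration_s * spec$truncate_fraction
  m <- floor(dur) - 9
  if (m < 1) {
    stop(sprintf("realized duration %.1f s yields no analysis windows", dur))
  }
  u <- spec$truncate_fraction * ((seq_len(m) - 0.5) / m)^spec$warp
  fade_u <- crossfade_windows * spec$truncate_fraction / m
  feats <- pathway_templates_at(dict, pathway, u, fade_u = fade_u)
  if (spec$noise_sd > 0) {
    feats <- with_seed(spec$seed, {
      pmax(feats + matrix(rnorm(length(feats), 0, spec$noise_sd),
                          nrow(feats)), 0)
    })
  }
  nb <- normalize_band_blocks(feats, dict$band_index)
  out <- fc_series(nb$features, n_channels = dict$n_channels,
                   bands = dict$bands,
                   window_times = as.numeric(seq_len(m) - 1),
                   missing_windows = nb$degenerate)
  attr(out, "duration_s") <- dur
  out
}

# per-channel source weights for one state and band: leading non-negative
# eigenvector of the state's band connectivity matrix (exact for rank-1
# templates, a best rank-1 proxy otherwise), scaled to max 1
state_band_weights <- function(dict, state_id, band) {
  n <- dict$n_channels
  n_pairs <- n * (n - 1) / 2
  block <- dict$states[[state_id]][((band - 1) * n_pairs + 1):(band * n_pairs)]
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- block
  A <- A + t(A)
  a <- rep(1 / sqrt(n), n)
  for (it in 1:50) {
    a2 <- pmax(A %*% a, 0)
    nrm <- sqrt(sum(a2^2))
    if (nrm == 0) break
    a2 <- a2 / nrm
    if (max(abs(a2 - a)) < 1e-10) { a <- a2; break }
    a <- as.numeric(a2)
  }
  a / max(a, 1e-12)
}

#' Realize a raw multichannel iEEG seizure from its latent pathway
#'
#' Renders a voltage matrix whose estimated band coherence correlates with
#' the latent state templates: for each band, all channels share one
#' band-limited Gaussian source, mixed into each channel with
#' state-dependent weights (the leading non-negative eigenvector of the
#' state's band connectivity matrix), plus independent white channel noise.
#' Channel pairs with large template weight therefore share the band source
#' strongly and show high band coherence.
#'
#' @param dict,pathway,spec as in [realize_fc_series()]; `rank1` dictionary
#'   structure gives the cleanest template recovery.
#' @param fs sampling frequency in Hz, at least 400 so the 80-150 Hz band
#'   is resolvable.
#' @param channel_noise_sd standard deviation of the independent white
#'   channel noise (sources have unit variance).
#' @return a [seizure_recording()].
#' @export
realize_raw_seizure <- function(dict, pathway, spec, fs = 512,
                                channel_noise_sd = 0.1) {
  stopifnot(inherits(dict, "state_dictionary"),
            inherits(pathway, "latent_pathway"),
            inherits(spec, "seizure_spec"))
  if (fs / 2 <= max(dict$bands)) {
    stop("fs is below the Nyquist rate for the highest frequency band")
  }
  if (fs < 400) stop("fs must be at least 400 Hz")
  dur <- spec$duration_s * spec$truncate_fraction
  nsamp <- round(dur * fs)
  n <- dict$n_channels
  n_bands <- nrow(dict$bands)
  with_seed(spec$seed, {
    # band-limited unit-variance sources
    sources <- vapply(seq_len(n_bands), function(b) {
      bf <- signal::butter(2, dict$bands[b, ] / (fs / 2), type = "pass")
      s <- signal::filtfilt(bf, rnorm(nsamp + 2 * fs))[(fs + 1):(fs + nsamp)]
      s / sd(s)
    }, numeric(nsamp))
    # per-sample pathway position and state (hard switching)
    u <- spec$truncate_fraction *
      (((seq_len(nsamp)) - 0.5) / nsamp)^spec$warp
    bounds <- cumsum(pathway$dwell_fractions)
    seg <- pmin(length(bounds),
                findInterval(u, c(0, bounds), rightmost.closed = TRUE))
    state <- pathway$state_sequence[seg]
    weights <- lapply(unique(state), function(k) {
      vapply(seq_len(n_bands), function(b) state_band_weights(dict, k, b),
             numeric(n))
    })
    names(weights) <- as.character(unique(state))
    data <- matrix(0, n, nsamp)
    for (k in unique(state)) {
      idx <- which(state == k)
      wk <- weights[[as.character(k)]]          # n x n_bands
      data[, idx] <- data[, idx] + wk %*% t(sources[idx, , drop = FALSE])
    }
    data <- data + matrix(rnorm(n * nsamp, 0, channel_noise_sd), n, nsamp)
    seizure_recording(data, fs = fs)
  })
}

#' Inject signal dropouts into a recording
#'
#' Replaces the affected samples with a flat (constant) signal — the value
#' at the interval onset — on the requested channels, and marks them in the
#' recording's missing mask. Intervals must lie within the recording and
#' must not overlap; an empty spec returns the recording unchanged.
#'
#' @param rec a [seizure_recording()].
#' @param dropout_spec data frame with columns `start_s`, `end_s` (seconds
#'   from the start of `data`, half-open) and optionally `channels` (a list
#'   column of channel index vectors; missing or `NA` means all channels).
#' @param seed unused placeholder kept for interface symmetry with the
#'   other generators (dropout injection is deterministic).
#' @return the modified recording.
#' @export
inject_dropout <- function(rec, dropout_spec, seed = NULL) {
  stopifnot(inherits(rec, "seizure_recording"))
  if (is.null(dropout_spec) || nrow(dropout_spec) == 0) return(rec)
  stopifnot(all(c("start_s", "end_s") %in% names(dropout_spec)))
  nsamp <- ncol(rec$data)
  a <- round(dropout_spec$start_s * rec$fs) + 1L
  b <- round(dropout_spec$end_s * rec$fs)
  if (any(a < 1L) || any(b > nsamp) || any(b < a)) {
    stop("dropout intervals out of range")
  }
  ord <- order(a)
  if (any(a[ord][-1] <= b[ord][-length(b)])) {
    stop("dropout intervals overlap")
  }
  for (i in seq_len(nrow(dropout_spec))) {
    chans <- if ("channels" %in% names(dropout_spec)) {
      ch <- dropout_spec$channels[[i]]
      if (is.null(ch) || all(is.na(ch))) seq_len(nrow(rec$data)) else ch
    } else seq_len(nrow(rec$data))
    rec$data[chans, a[i]:b[i]] <- rec$data[chans, a[i]]
    rec$missing_mask[chans, a[i]:b[i]] <- TRUE
  }
  rec
}
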