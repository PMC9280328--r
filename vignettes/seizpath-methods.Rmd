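---
title: "Quantifying seizure pathway and duration variability with seizpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seizure pathway and duration variability with seizpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizpath)
```

## The analysis in one paragraph

A focal seizure recorded with intracranial EEG (iEEG) can be summarized by
two very different quantities: its *pathway* — the trajectory its functional
network takes through connectivity space from onset to termination — and its
*duration*. Within a single subject, both vary from seizure to seizure, and
the relationship between the two is informative: pairs of seizures can share
a pathway but differ in duration (*elasticity*: the same route run at a
different speed), differ in pathway while lasting equally long
(*semblance*), or one seizure can run only the first part of the other's
route and stop proportionally earlier (a *truncation pair*). `seizpath`
implements the full per-subject analysis: time-varying functional
connectivity, pairwise pathway dissimilarities and duration differences, a
permutation test of their association, truncation detection, the four-way
pair taxonomy, duration-population clustering, and a 2-D embedding for
visualization — together with a synthetic seizure-cohort generator that
provides ground truth for every stage.

## From voltage to pathways

**Preprocessing.** Recordings at mixed sampling rates are downsampled to
the lowest rate (`resample_to_common()`), noisy channels are excluded via a
user-supplied list (channel screening is a visual-inspection step and is
deliberately an *input* here), short missing segments (< 0.05 s) are
linearly interpolated, all channels are re-referenced to the common
average, and each channel is bandpass filtered 1–150 Hz with a 4th-order
Butterworth run forward–backward (zero phase; the effective magnitude
response is 8th-order) plus 2 Hz-wide band-stop notches at the mains
harmonics. For chronic implants with telemetry dropouts,
`detect_dropout_windows()` flags 1/10 s windows in which at least half the
montage (8 of 16 channels) is flat — per-channel line length
$L = \frac{1}{T-1}\sum_i |x_{i+1}-x_i| \le 0.5$ — along with both
neighbouring windows.

**Connectivity.** `compute_fc_series()` slides a 10 s window at 1 s steps
across the seizure, so a seizure of duration $d \ge 10$ s yields
$m = \lfloor d \rfloor - 9$ windows. In each window the band-averaged
coherence

$$C_{i,j} = \frac{\left|\sum_{f=f_1}^{f_2} P_{i,j}(f)\right|^2}
  {\sum_f P_{i,i}(f)\,\sum_f P_{j,j}(f)}$$

is computed for the six canonical bands (delta 1–4, theta 4–8, alpha 8–13,
beta 13–30, gamma 30–80, high gamma 80–150 Hz), with the auto- and
cross-spectra estimated by Welch's method (2 s subwindows, 1 s overlap,
Hamming taper) and summed over in-band bins *before* the ratio is formed —
not bin-wise coherence averaged afterwards. Each coherence matrix is
vectorized (upper triangle, $(n^2-n)/2$ entries per band) and each band
block is normalized to unit L1 norm, giving $6(n^2-n)/2$ non-negative
features per window. Band membership of FFT bins is half-open
($f_1 \le f < f_2$), so printed band edges such as 4 Hz are not counted
twice. A window missing at least 5 of its nine 2 s subwindows is marked
missing; windows missing fewer are computed from the remaining subwindows,
and seizures retaining any missing window are excluded outright
(`exclude_incomplete_seizures()`).

**Denoising (optional).** `fit_stability_nmf()` factorizes the subject's
concatenated windows $V \approx WH$ with non-negative HALS under a
stability criterion: for every candidate rank, several restarts are fit
from random initializations, the basis vectors of each restart pair are
matched one-to-one by the assignment maximizing total cosine similarity,
and the pair is scored by its *minimum* matched cosine. The selected rank
is the largest whose mean score reaches 0.9. We score by the minimum
rather than the mean of the matched cosines deliberately: on planted
low-rank data, surplus components at overfit ranks arise as near-duplicates
or splits of true components and match each other at cosine ≈ 0.9–1.0, so
a mean over components stays above threshold and the selection drifts
upward, while the weakest matched component exposes the irreproducibility
immediately (0.99 at the planted rank versus 0.6–0.8 one rank above it, in
our tests). Ties among assignments are irrelevant because only the
similarity values enter the score. The matching is exact (permutation
enumeration) up to rank 7 — comfortably covering the default range 1–6 —
and greedy above, where well-separated bases make greedy and optimal
coincide. Reconstructions $\hat V = WH$ are *not* re-normalized per band by
default. The whole pipeline also runs with denoising disabled
(`pipeline_config(nmf = FALSE)`), which oracle tests rely on.

## Comparing seizures

**Pathway dissimilarity.** `dtw_dissimilarity()` aligns two connectivity
time series with classic dynamic time warping — unit steps
(match/insert/delete), both endpoints anchored, local cost the L1
(cityblock) distance between window feature vectors, no warping-window
constraint — and returns the total optimal cost divided by $K$, the number
of aligned window pairs on the optimal path (the length of the warped
series). This is the average L1 distance between the warped series; because
repeating a window is free, a pathway and any repeat-stretched copy of it
are at dissimilarity exactly 0, which is what makes the measure blind to
pure rate changes (elasticity). When several warping paths attain the
minimal total cost their lengths can differ; the backtrack prefers the
diagonal step on ties, so a shortest optimal path is reported, and tests
only assert the (unique) total cost plus membership of $K$ in the optimal
set. `pathway_dissimilarity_matrix()` assembles the symmetric $s \times s$
matrix over a subject's seizures.

**Duration difference.** $|\ln l_i - \ln l_j| = |\ln(l_i/l_j)|$ depends
only on the *ratio* of durations: 20 s vs 40 s equals 60 s vs 120 s. The
similarity threshold 0.2 used by the taxonomy corresponds to an
$e^{0.2} = 1.22$-fold increase over the shorter seizure. The measure is a
metric on $\ln l$ (the pathway dissimilarity, an averaged DTW cost, need
not satisfy the triangle inequality — documented, not asserted).

**Association.** `spearman_upper()` rank-correlates the
$s(s-1)/2$ upper-triangular entries of the two matrices;
`mantel_test()` builds the null by jointly permuting rows and columns of
one matrix (which preserves its internal distance structure) and reports
the one-sided $p = (\#\{\rho_{perm} \ge \rho_{obs}\} + 1)/(n_{perm}+1)$.
The add-one convention guarantees $p \in (0,1]$ even when the observed
statistic is maximal; when fewer than `n_perm` distinct permutations exist
($s \le 7$ at the 10 000 default) the test enumerates all $s!$ permutations
exactly instead. Across subjects, `bh_fdr()` applies Benjamini–Hochberg
step-up at $\alpha = 0.05$.

**Truncation detection.** `find_truncation_pairs()` first groups nearly
identical pathways (UPGMA, dendrogram cut at dissimilarity 1, merges at
exactly the cut height kept together) and takes each group's centroid — the
member with the lowest mean dissimilarity to the rest — as its
representative. An ordered group pair (A, B) is a truncation when (i) every
A seizure is strictly shorter than every B seizure, (ii) every A seizure
has strictly smaller *pathway size* (the maximum cityblock distance between
any two of its windows; zero for a single window) than every B seizure, and
(iii) scanning $m$ from 1, the partial dissimilarity between A's centroid
and the first $m$ windows of B's centroid dips to $\le 1$ somewhere. Ties
fail (i) and (ii) — a conservative reading that keeps the relation
antisymmetric. All $|A|\cdot|B|$ seizure pairs of a flagged group pair
count toward the subject's truncation-pair proportion.

**Taxonomy.** `classify_pairs()` partitions pairs by two inclusive
thresholds (pathway $\le 1$, duration $\le 0.2$) into
concordant-similar, elastic, semblant and concordant-different. The
defaults are the conventional operating point;
`calibrate_duration_threshold()` reproduces the data-driven alternative of
choosing the duration threshold as the pooled quantile matching the
prevalence of similar pathways.

**Duration populations.** `cluster_durations()` log-transforms the
durations, scans k-means over $k = 1, \dots, \min(s, 10)$ (10 restarts per
$k$) and selects $k$ with the gap statistic: reference sets drawn uniformly
over the observed range of the 1-D log durations (the usual PCA alignment
of the reference box is a no-op in one dimension), standard errors with the
$\sqrt{1 + 1/B}$ correction, and the firstMaxSE rule — the smallest $k$
with $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - \mathrm{SE}(k+1)$. The scan
stops at $s-1$: the all-singleton solution has zero within-dispersion by
construction (and Hartigan–Wong k-means requires $k < n$), so it is never
an informative optimum. When $k \ge 2$, `cluster_pathways()` cuts the
pathway UPGMA dendrogram into the same number of groups and
`partition_agreement()` compares the partitions with the Rand index and
adjusted Rand index, each with a 10 000-permutation one-sided null.

A detection boundary worth knowing: for a two-component location mixture in
one dimension with component sd $\sigma$ and mode separation $s\sigma$,
splitting at $k = 2$ reduces the within-cluster dispersion by the factor
$1 + s^2/4$, whereas a uniform reference reduces by the factor 4. The gap
therefore only starts favouring $k = 2$ once $s > 2\sqrt{3} \approx 3.46$,
and in simulation detection rises from ~15% of seeds at $s = 3$ through
~55% at $s = 3.5$ and ~95% at $s = 4$ to 100% at $s = 5$. Bimodal duration
structure separated by only ~3 within-mode standard deviations is thus
*expected* to go undetected by this (deliberately conservative) selector —
a property of the method, inherited from its reference distribution, not an
implementation artefact. Package tests that exercise the clustering
machinery therefore use 5-sd-separated mixtures, above the boundary.

**Embedding.** `sammon_map()` minimizes the Sammon stress of the pairwise
L1 distances between all seizure windows, from a classical-MDS start with a
monotone (step-halved) descent, 500 iterations, relative tolerance
$10^{-9}$. Zero off-diagonal distances (duplicate windows) are floored at
$10^{-6} \times \max d$ since the stress weights are $1/d_{ij}$. The
embedding is for visualization only; no downstream statistic consumes it.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code — the ground-truth bed for
everything above. Its model:

* a **dictionary** of latent network states (`make_dictionary()`), each a
  band-specific connectivity template with unit-L1 band blocks, drawn
  sparsely and redrawn until all states are at least `margin = 2` apart in
  cityblock distance (an impossible margin fails explicitly after a bounded
  number of redraws);
* a **latent pathway** per seizure route: an ordered state sequence with
  positive dwell fractions summing to 1. Pathways of one cohort use
  disjoint state subsets, which makes cross-pathway dissimilarities large
  by construction;
* each **seizure** realizes its pathway at some duration (windows follow
  the same $m = \lfloor d\rfloor - 9$ rule as the connectivity stage),
  optionally time-warped (pathway position traversed as $u^{w}$, a monotone
  dwell rescaling that changes speed but not route), truncated to the
  leading `truncate_fraction` of dwell mass with proportionally shortened
  duration, cross-faded linearly between states over one window (hard
  switches between network regimes would be unrealistically discontinuous),
  perturbed with additive Gaussian feature noise truncated at zero, and
  re-normalized per band — so the invariants of real features hold exactly;
* **durations** are lognormal, by default $\ln l \sim
  \mathcal N(\ln 60, 0.5^2)$ — log durations are near-normal in real
  cohorts, and a 60 s centre with ~±65% spread is typical of focal
  seizures — optionally a two-component mixture with modes `bimodal_sep`
  log-sds apart, either mixed at random or tied to pathway identity;
* **planted pairs** claim dedicated seizures: elastic pairs share a pathway
  with a log-duration ratio of 0.7 (about two-fold, well past the 0.2
  threshold) and a mild warp; semblant pairs take one seizure from each of
  two pathways at identical durations; truncation pairs realize a prefix
  child of a parent seizure. The truncation prefix is capped inside the
  parent's first dwell segment: a prefix spanning several states can tie
  the parent's pathway *size* exactly (the group criteria use strict
  inequalities, so an exact tie would mask a genuine truncation), whereas a
  one-state prefix has near-zero size and is detected robustly.

Raw-signal realization (`realize_raw_seizure()`) renders each seizure as
band-limited Gaussian sources shared across channels with state-dependent
mixing weights (the leading non-negative eigenvector of the state's band
connectivity matrix — exact for rank-1 structured dictionaries) plus
independent white channel noise, at `fs >= 400` Hz so the 80–150 Hz band is
resolvable. This is the simplest generative model with controllable band
coherence; it is *not* a biophysical seizure model, and the generator makes
no attempt at realistic waveform morphology, postictal suppression, or
interictal background.

What passing tests on this generator do and do not show: they verify the
measures and decision rules — DTW against exhaustive enumeration, recovery
of planted structure, calibration of the permutation tests — under a
stylized model in which pathway membership is discrete and cross-pathway
distances are large. Real seizure pathways vary continuously, overlap
between "routes" is partial, and channel coverage differs per subject; the
generator says nothing about those regimes, which is why thresholds (1.0,
0.2) are exposed as parameters rather than re-derived here.

## Numerical choices and degenerate inputs

* Windowing is half-open everywhere ([start, start + length)), with the
  seizure clock starting at the onset sample; the final partial
  connectivity window is dropped rather than padded.
* An all-zero band block in a window is left at zero (no division) and the
  window is flagged missing rather than silently normalized.
* Constant dissimilarity matrices make rank correlation undefined; the
  association functions warn and return `NA` rather than a number.
* Permutation p-values use the add-one convention throughout, so no test
  ever reports $p = 0$; exhaustive enumeration replaces sampling when the
  permutation space is smaller than the requested draws.
* All stochastic stages take explicit seeds, run under a temporarily
  swapped RNG state (`withr`), and are bit-reproducible: identical
  config + seed gives identical cohorts, factorizations, and p-values.
* Dendrogram cuts at a height are inclusive (merges at exactly the cut
  height stay merged), matching the "dissimilarity ≤ 1" reading of the
  grouping rule.

## Problem sizes used by the tests and acceptance script

Simulation-based checks run at sizes chosen to make each property sharp yet
quick: 200 random DTW instances up to 5×5 windows against exhaustive
enumeration; Mantel type-I calibration over 1000 independent-null runs of
200 permutations each ($s = 10$); taxonomy and truncation recovery over 5
cohort seeds (12 and 10 seizures per cohort, feature noise sd 0.002);
gap-statistic recovery over 20 seeds of 100 log-durations with 200
reference distributions; stability-NMF recovery of a planted rank-3
factorization (60 features × 80 windows) over 5 seeds. The full-pipeline
demonstrations use cohorts of 16 and 50 seizures with 10 000 permutations,
the analysis default.

## Known limitations

* The stability-NMF solver is a deliberately simple HALS with restart-based
  rank selection; it is a stable low-rank denoiser, not a reimplementation
  of any particular factorization toolbox.
* The truncation criteria inherit the grouping: if the UPGMA cut merges a
  truncated child with its parent group (high noise, cut too lax), the pair
  is invisible to the ordered-group scan.
* The gap-statistic selector is conservative near its detection boundary
  (see above); weakly separated duration populations will be reported as a
  single mode.
* Sammon stress is non-convex; different initial configurations can give
  different (mirrored/rotated) embeddings. Coordinates are reproducible
  under a fixed seed but are only defined up to isometry.
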