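# seizpath

Within-subject variability of seizure pathways and durations from
intracranial EEG (iEEG).

## The problem

A subject's focal seizures are not carbon copies of each other. Two things
vary from seizure to seizure: the **pathway** — the trajectory the seizure's
functional network takes through connectivity space from onset to
termination — and the **duration**. How the two co-vary is mechanistically
informative. A pair of seizures can:

* follow similar pathways for similar durations, or different pathways for
  different durations (*concordant* pairs — pathway and duration carry the
  same message);
* follow the **same pathway at different speeds** (*elasticity*);
* follow **different pathways that happen to last equally long**
  (*semblance*);
* or one seizure can run only the **beginning of the other's pathway and
  stop proportionally earlier** (a *truncation pair*).

`seizpath` implements the complete per-subject analysis for epilepsy
researchers working with iEEG seizure clips (epilepsy monitoring unit
recordings, chronic implants, or animal models), plus a synthetic
seizure-cohort generator with known ground truth so that every stage of the
pipeline is testable.

## The measures at its core

* **Seizure pathway**: sliding-window functional connectivity. A seizure of
  duration *d* ≥ 10 s yields *m* = ⌊*d*⌋ − 9 windows (10 s window, 9 s
  overlap); each window holds band-averaged coherence

  $$C_{i,j} = \frac{\bigl|\sum_{f=f_1}^{f_2} P_{i,j}(f)\bigr|^2}
    {\sum_f P_{i,i}(f)\sum_f P_{j,j}(f)}$$

  for all channel pairs in six bands (delta through high gamma, 1–150 Hz),
  Welch-estimated (2 s subwindows, 1 s overlap), vectorized and
  L1-normalized per band: 6(*n*²−*n*)/2 non-negative features per window.
* **Pathway dissimilarity**: dynamic time warping between two seizures'
  feature series (unit steps, L1 local cost, endpoints anchored), returning
  the average L1 distance along the optimal warping path. Pure
  rate-changes are free — a pathway and a repeat-stretched copy are at
  dissimilarity 0.
* **Duration difference**: |ln *l<sub>i</sub>* − ln *l<sub>j</sub>*|, a
  ratio measure (20 s vs 40 s ≡ 60 s vs 120 s = ln 2). The similarity
  threshold 0.2 corresponds to an e<sup>0.2</sup> = 1.22-fold increase.
* **Association**: Spearman correlation of the two pairwise matrices'
  upper triangles, tested with a one-sided Mantel permutation test
  (10 000 permutations), Benjamini–Hochberg corrected across subjects.
* **Truncation pairs**: UPGMA pathway groups (dendrogram cut at 1), group
  centroids, strict shorter-duration and smaller-pathway-size criteria, and
  a partial-pathway DTW scan against prefixes of the larger pathway.
* **Duration populations**: k-means on log durations with the gap statistic
  (uniform reference, firstMaxSE), compared to same-*k* UPGMA pathway
  clusters via Rand/adjusted Rand indices with permutation nulls.
* **Visualization**: Sammon mapping of the L1 distances between all seizure
  windows.

Stability non-negative matrix factorization (`fit_stability_nmf()`) is
available to denoise the concatenated connectivity windows before the
pairwise stages; the pipeline runs with or without it.

## Worked example

Generate a synthetic subject whose two pathways carry different duration
modes, with one planted elastic pair and two planted truncations, and run
the full pipeline:

```r
library(seizpath)

cfg <- cohort_config(n_pathways = 2, seizures_per_pathway = 8,
                     n_elastic = 1, n_truncated = 2,
                     bimodal = TRUE, bimodal_sep = 5,
                     bimodal_by_pathway = TRUE, noise_sd = 0.002)
cohort <- generate_cohort(cfg, seed = 1)
cohort
#> <synthetic_cohort> 16 seizures on 2 pathways (seed 1)
#>   planted pairs: elastic=1 truncated=2

res <- run_pipeline(cohort$fc, cohort$durations_s,
                    pipeline_config(n_perm = 10000, n_ref = 200, seed = 2))
res
#> <seizpath_results> 16 seizures, 120 pairs
#>   pathway-duration association: rho = 0.540, Mantel p = 0.0005999
#>   truncation-pair proportion: 0.117
#>   duration populations: k = 1
#> <pair_taxonomy> 120 pairs (thr_path = 1, thr_dur = 0.2)
#>   similar-similar        14 (11.7%)
#>   elastic                28 (23.3%)
#>   semblant                0 (0.0%)
#>   different-different    78 (65.0%)
```

Reading the output: the subject's pathway dissimilarities and duration
differences are positively rank-correlated (rho = 0.54) and the Mantel test
rejects chance (p ≈ 6 × 10⁻⁴) — here because the two pathways carry
different duration modes and the planted truncations make short seizures
travel short pathways. 11.7% of seizure pairs are related by a truncation
(the two planted child/parent group pairs). The taxonomy counts every pair
once: 23.3% of pairs are elastic (similar pathway, >1.22-fold duration
ratio — the planted pair plus within-pathway duration spread), none are
semblant in this draw, and the rest are concordant. With 16 seizures the
conservative gap statistic reports a single duration population;
`scripts/acceptance.R` includes a 50-seizure demonstration where the two
modes are detected (k = 2) and agree with the pathway clusters
(ARI ≈ 0.84, permutation p ≈ 10⁻⁴).

`run_pipeline(..., out_dir = "results/subject01")` writes the pairwise
matrices (CSV), association, truncation, taxonomy and duration-population
reports (JSON), embedding coordinates (CSV), and a run log. All stages are
seed-reproducible.

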