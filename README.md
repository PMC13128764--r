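# cortclust

Unsupervised phenotyping of early postoperative serum cortisol
trajectories after transsphenoidal resection of ACTH-secreting pituitary
adenomas (Cushing's disease). After surgery, cortisol is typically drawn
every 6 hours and clinicians watch for a "crash" toward low values; in
practice the series are short, irregular, and truncated as soon as
replacement steroids begin, and there is no standard way to read them.
`cortclust` is aimed at endocrine/neurosurgical outcomes researchers who
want to ask: *do these incomplete trajectories fall into reproducible
patterns, and do the patterns relate to anything clinical?*

## What it does

The core is **k-POD clustering** — k-means made robust to missing data by
alternating minimization. With `x_i` a patient's cortisol vector on the
6-hourly grid, partition `C_1..C_K` and centroids `mu_k`:

1. complete each missing cell with the assigned centroid's coordinate,
2. run Lloyd updates (assign to nearest centroid, recompute centroids) on
   the completed matrix,
3. repeat until assignments stabilize; every step is non-increasing in the
   completed-data objective.

Cluster quality is summarized by the fit-integrity statistic, computed on
observed cells only:

    TSS  = sum_i || x_i - mu ||^2
    WCSS = sum_k sum_{x_i in C_k} || x_i - mu_k ||^2
    fit  = 1 - WCSS / TSS

Around the core, the package provides

* `select_k()` — elbow selection of the cluster count from the fit curve,
* `two_pass_cluster()` — cluster on the full grid, find the contiguous
  window of significant per-timepoint separation (one-way ANOVA +
  Benjamini–Hochberg), re-cluster inside that window,
* `diagnose_convergence()` — subsample-stability diagnostics that flag
  small homogeneous groups where clustering is not trustworthy,
* `bin_to_grid()`, `censor_after_steroids()`, `derive_features()` —
  gridding, steroid censoring, and trajectory features (initial 6 h
  cortisol, nadir, descent velocity `(c(6h) - c(18h))/12`),
* `welch_t()`, `oneway_anova[_summary]()`, `chisq_2xk()`, `bh_adjust()`,
  `test_battery()` — the group-comparison battery, including
  summary-statistic entry points for working from reported summary tables,
* `generate_cohort()` — a synthetic-cohort generator (trajectory mixture +
  steroid censoring + sporadic missingness + covariates) so the whole
  pipeline runs without any patient-level data,
* `run_full()` — end-to-end orchestration writing labels, centroids,
  window, test battery, figures and a run manifest,
* broom-style `tidy()`/`glance()`/`augment()` and
  `autoplot()`/`plot_*()` for every result type.

## Worked example

```r
library(cortclust)

cohort <- generate_cohort(77, counts = c(23, 15, 39), seed = 1)
cohort
#> <cortisol_cohort> 77 patients, grid 6-36 h (6 timepoints)
#>   observed cells: 377 / 462 (81.6%); steroid-censored patients: 33
#>   true labels: A=23 B=15 C=39

res <- two_pass_cluster(cohort, k = "auto", seed = 1)
glance(res)
#> # A tibble: 1 x 7
#>       k window_start window_end window_size fit_pass1 fit_pass2 converged
#> 1     3            6         36           6     0.641     0.641 TRUE

tidy(res$pass2)
#> # A tibble: 3 x 8
#>   cluster  size    h6   h12   h18   h24   h30   h36
#> 1       1    23  25.7  36.4 32.3  14.7   4.72  3.70
#> 2       2    12  61.5  64.0 23.8  18.1  15.2  12.9
#> 3       3    42  26.2  11.8  5.85  4.09  3.02  2.89
```

The elbow picks K = 3 (fit curve 0, 0.44, 0.64, 0.71, 0.77, 0.80 for
K = 1..6), every timepoint from 6 to 36 h separates the clusters under the
BH threshold, and the three mean curves are the classic phenotypes: low
start with a slow fall (cluster 1), high start with a moderate fall
(cluster 2), low start with a rapid fall (cluster 3). Trajectory features
make the same point:

```r
derive_features(cohort$measurements) |>
  dplyr::inner_join(tidy(res), by = "patient_id") |>
  dplyr::group_by(.cluster) |>
  dplyr::summarise(n = dplyr::n(),
                   initial = mean(initial_cortisol, na.rm = TRUE),
                   velocity = mean(descent_velocity, na.rm = TRUE))
#>   .cluster     n initial velocity
#> 1 1           23    25.7   -0.513     # cortisol rises before it falls
#> 2 2           12    61.5    2.96
#> 3 3           42    26.2    1.78
```

`autoplot(res$pass1)`, `plot_cluster_means()`, `plot_spaghetti()` and
`plot_missingness()` draw the corresponding figures, and `run_full(dir,
seed = 1)` writes the whole artifact set in one call.

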