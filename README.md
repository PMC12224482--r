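# icedstab

Longitudinal stability of repeated measurements via intra-class effect
decomposition.

When a structural brain measure (or any other quantity) is collected twice
with years in between, the test-retest agreement mixes measurement
reliability with true change. Researchers planning or interpreting
longitudinal studies — multi-site developmental imaging cohorts in
particular — need to know *how much* of the observed variance reflects stable
individual differences, whether that answer differs across brain regions,
measures, and testing sites, and what it implies for study design. `icedstab`
is for them.

## The model

The package fits a two-timepoint covariance-structure model by maximum
likelihood: the 2x2 covariance of the occasions is decomposed into a
between-subjects component σ²B (loading 1 on both occasions) and
occasion-specific error σ²E, constrained equal across occasions by default.
Longitudinal stability is then

    ICC  = σ²B / (σ²B + σ²E)                 (single measurement)
    ICC2 = σ²B / (σ²B + σ²E / N)             (average of N repeats)

with χ² = (n−1)·F_ML fit statistics, CFI against an independence baseline,
and profile-likelihood confidence intervals for the ICC. On top of the
per-slice fit sit:

* **Stability maps** (`fit_region_map`, `summarize_map`): batch fits over
  measures × regions × sites with failure-tolerant status codes.
* **Multigroup comparisons** (`model_comparison_series`, `comparison_grid`):
  four models across sites (both components equal / σ²B free / σ²E free /
  both free) and five ΔCFI comparisons that localise site differences to a
  variance component.
* **Rank-order stability** (`rank_order_stability`): Shrout-Fleiss ICC(2,1)
  and ICC(3,1) of the estimate maps themselves.
* **Lobe aggregation** (`aggregate_lobes`): mean thickness, summed area and
  volume, with an editable YAML region→lobe mapping.
* **Design planning** (`required_timepoints`, `attenuated_correlation`,
  `sample_size_for_correlation`): how many repeats reach a target ICC2, how
  much imperfect stability attenuates correlations, and what that costs in
  participants.
* **A synthetic generator** (`simulate_dataset`): multi-site two-timepoint
  data with known variance components, so every stage has a ground-truth test
  bed.

## Worked example

```r
library(icedstab)

cfg <- small_config(n_sites = 5, n_per_site = 400, n_regions = 8,
                    site_error_spread = 3, seed = 7)
d <- simulate_dataset(cfg)

fit_iced(summarize_two_timepoint(d[d$region == "region01", ]))
#> Two-timepoint variance decomposition (equal error variances)
#>   sigma_b2 = 0.02197   sigma_e2 = 0.01896
#>   ICC = 0.537  ICC2(N=2) = 0.699  profile CI [0.505, 0.567]
#>   chisq(df=1) = 2.917   CFI = 0.9972   status: ok
```

About 54% of this region's observed variance is stable between-subjects
signal (the generator's truth for region01 is ICC = .55, inside the
interval); averaging the two occasions would lift the construct-level
stability to .70.

```r
summarize_map(fit_region_map(d, grouping = "pooled"))
#>     measure n_ok mean_icc min_icc max_icc mean_icc2 min_icc2 max_icc2
#> 1 thickness    8    0.716   0.537   0.899     0.829    0.699    0.947

model_comparison_series(d[d$region == "region05", ], "site")
#> Multigroup model comparisons (threshold 0.02 )
#>   comparison delta_cfi  flag
#> 1          A    0.0049 FALSE
#> 2          B    0.0954  TRUE
#> 3          C    0.0998  TRUE
#> 4          D    0.0006 FALSE
#> 5          E    0.1004  TRUE
```

Comparisons C and E flag while A does not: letting *error* variance differ by
site improves fit meaningfully, letting *between-subjects* variance differ
does not — exactly the structure this dataset was generated with (equal σ²B,
3-fold σ²E spread across sites).

```r
required_timepoints(icc = 0.54)
#> [1] 8

attenuation_power_report(
  data.frame(label = c("parahippocampal", "temporalpole"),
             rel_region = c(0.9, 0.54)))
#>             label rel_region r_true rel_measure power alpha r_observed
#> 1 parahippocampal       0.90    0.3         0.9   0.8  0.05       0.27
#> 2    temporalpole       0.54    0.3         0.9   0.8  0.05       0.21
#>   n_required pct_extra_participants
#> 1        105                    0.0
#> 2        175                   66.7
```

A region at ICC = .54 needs eight repeated scans before the averaged measure
clears "excellent" (ICC2 > .9) stability, and detecting a true r = .3 through
it takes 175 participants instead of 105 — two thirds more — purely because of
the stability gap.

`run_pipeline(pipeline_config(simulation = cfg, out_dir = "out"))` runs all
stages end to end and writes the tables plus a reproducibility manifest.

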