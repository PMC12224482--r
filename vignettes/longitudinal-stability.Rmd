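---
title: "Mapping longitudinal stability with intra-class effect decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping longitudinal stability with intra-class effect decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icedstab)
```

## The model

When the same structural measure is collected twice, years apart, the
difference between the two values mixes measurement error with genuine change.
`icedstab` decomposes the 2x2 covariance of the two occasions into a
between-subjects component $\sigma^2_B$ — variance attributable to stable
individual differences, loading 1 on both occasions — and occasion-specific
error $\sigma^2_E$:

$$\Sigma(\theta) = \begin{pmatrix}
\sigma^2_B + \sigma^2_{E} & \sigma^2_B \\
\sigma^2_B & \sigma^2_B + \sigma^2_{E}
\end{pmatrix}.$$

The default model constrains the error variance to be equal at both occasions
(1 degree of freedom against the three observed moments); freeing the two
error variances saturates the model, which then reproduces the sample
covariance exactly. Means are saturated and ignored: the model is about
rank-ordering people, not about mean change, so a uniform shift between
occasions (every participant's cortex thinning by the same amount) does not
touch any estimate.

Longitudinal stability of a single measurement is the intraclass correlation

$$ICC = \frac{\sigma^2_B}{\sigma^2_B + \sigma^2_E},$$

and the construct-level stability of the average of $N$ independent repeats
uses the effective error $\sigma^2_E/N$:

$$ICC2 = \frac{\sigma^2_B}{\sigma^2_B + \sigma^2_E/N},$$

so components with $\sigma^2_B = \sigma^2_E$ (ICC = .5) give ICC2 = .66 at two
occasions and .75 at three. Because two timepoints cannot separate error from
individual differences in the *rate* of change, any such differences inflate
$\sigma^2_E$ and depress the recoverable ICC — the generator exposes this
directly through `slope_sd` (see below), and the estimate should be read as a
stability-reliability mixture, not pure measurement reliability.

## Estimation and numerical choices

Parameters are estimated by minimising the maximum-likelihood discrepancy
$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \log|S| -
2$, with $\chi^2 = (n-1)F_{ML}$ at the minimum (the Wishart convention for
covariance summaries; cross-checks against software using $n$ weighting must
account for the difference). The optimiser is a BFGS start from a neutral
moment split of the observed variance, polished by damped Newton steps with
the analytic gradient and Hessian until the step is negligible, so interior
solutions agree with the algebraic projection $\hat\sigma^2_B = s_{12}$,
$\hat\sigma^2_E = (s_{11}+s_{22})/2 - s_{12}$ to near machine precision. The
closed form is deliberately *not* used as the implementation: it serves as an
independent oracle in the test suite.

Further conventions, each chosen where the method itself leaves the choice
open:

* **Negative variance estimates** are permitted during optimisation (the
  common SEM practice), reported with a warning, and the ICC is clipped to
  $[0,1]$ for reporting; `allow_negative = FALSE` box-constrains at zero
  instead.
* **CFI baseline**: independence model (zero covariance, free variances),
  whose ML solution is closed-form, $\chi^2_b = (n-1)(-\log(1-r^2))$ on 1 df.
  For multigroup models the baseline is the sum of per-group independence
  models (df = G), consistent with the single-group choice.
* **Degenerate inputs**: a zero-variance slice returns a `degenerate` status
  with missing ICC rather than an error, so batch maps always complete. A
  singular-but-nonzero sample covariance (error-free data) has an undefined
  Wishart likelihood; the moment projection still identifies the components
  and the fit is returned with missing fit indices and the flagged interval
  $[1,1]$.
* **Confidence intervals** are profile likelihood on the ICC under the
  reparameterisation $(T, \rho) = (\sigma^2_B + \sigma^2_E,\, ICC)$. For fixed
  $\rho$ the discrepancy minimised over $T$ is closed-form, so the profile is
  exact and the bounds come from two scalar root-findings against the
  $\chi^2_1$ quantile. Boundary estimates yield one-sided flagged intervals.
  This is the package's default method; it is one of several intervals that
  could sit behind published ICC uncertainty ranges.

## Multigroup comparisons

To localise stability differences across sites (or scanner manufacturers: the
same code path with a different grouping column), four models are fitted
jointly over groups — both components equal across groups; $\sigma^2_B$ free;
$\sigma^2_E$ free; both free (which separates into per-group fits) — and five
CFI differences A-E are reported, each oriented towards the less-constrained
model. Flags on C (constrained vs error-varying) and E but not A indicate
error-driven site differences; A and E but not C indicate genuine
between-subjects differences. The .02 flag threshold is a convention, kept as
a configurable default, not a hard-coded rule.

The degrees of freedom follow $3G - p$ exactly (constrained $p=2$; partially
varying $p=G+1$; unconstrained $p=2G$), and the test suite asserts nesting
monotonicity of the $\chi^2$ chain on every run.

## What the generator emulates — and what it does not

`simulate_dataset()` draws from

$$y_{it} = \mu_r + \Delta_r 1[t{=}2] + b_i + s_i 1[t{=}2] + e_{it},$$

$b_i \sim N(0, \sigma^2_B(r))$, $s_i \sim N(0, \texttt{slope\_sd}^2)$,
$e_{it} \sim N(0, \sigma^2_{E_t}(site, r))$, Gaussian throughout — the ML
estimator assumes multivariate normality and non-Gaussian options are out of
scope. With `slope_sd = 0` and `error_timepoint_ratio = 1` the population
covariance is exactly the constrained model's $\Sigma(\theta)$, which is what
makes the generator a ground-truth test bed.

Two shipped profiles fix the study conditions:

* `abcd_like_config()`: 21 sites x 350 participants, the 68 Desikan-Killiany
  regions, three measures, scanner manufacturers assigned to sites in 13/3/5
  blocks. Per-region ICC ladders span thickness .54-.90, surface area
  .82-.97, volume .76-.97 — the ranges reported for large multi-site
  developmental samples — with per-site error multipliers spread 3-fold.
  Surface area and volume are generated in native units so the pipeline's
  rescaling (x .001 before fitting) is exercised; ICC, ICC2, $\chi^2$ and CFI
  are scale-equivariant, so rescaling only conditions the optimisation.
* `small_config()`: 5 sites x 400 participants, 8 regions, one measure, for
  routine runs. The full test suite, including the end-to-end pipeline at
  this scale, runs in well under a minute on one CPU; the stochastic
  simulation tests use 20-30 seeds per scenario and 200 replicates for
  recovery/coverage, sizes chosen to keep Monte-Carlo error comfortably
  inside the asserted margins.

Real data differ in ways the generator deliberately omits: values are
independent across regions given the site (no cortical covariance structure),
there is no missingness, no motion or artifact process, no site-by-measure
interaction beyond the error map, and participant identifiers are plain
zero-padded integers. Passing tests therefore demonstrate that the machinery
recovers known components under the model's own assumptions — not that any
particular empirical map is correct.

In the multigroup discrimination simulations the error spread is 4-fold
*below* the between-subjects variance ($\sigma^2_E$ from 0.25 to 1.0 against
$\sigma^2_B = 1$, i.e. ICCs from .5 to .8, the empirically realistic regime).
This matters: when error variance dominates, a free between-subjects
component can partially absorb total-variance differences and comparison A
picks up spillover even when only error truly varies.

## Rank-order stability, dispersion, and lobes

A site-grouped stability map can itself be treated as a measurement design:
are the same regions stable across sites, and the same sites stable across
regions? `estimate_matrix()` pivots the map (by convention, "by region" makes
regions the targets and sites the raters; "by site" swaps them — the two are
*not* interchangeable, and the suite asserts the asymmetry), and
`rank_order_stability()` computes Shrout-Fleiss ICC(2,1) (absolute agreement)
and ICC(3,1) (consistency) from two-way ANOVA mean squares. A constant rater
shift leaves ICC(3,1) at 1 while lowering ICC(2,1).

`dispersion_decomposition()` compares the variance, across one axis, of the
per-level medians of each component taken over the other axis — a compact
answer to "is heterogeneity region-driven (between-subjects variance) or
site-driven (error)?".

`aggregate_lobes()` collapses regions to lobes per participant and timepoint:
thickness by unweighted mean (a surface-area-weighted option exists but is
off by default, since the plain mean is the common reporting convention),
area and volume by sum, so total volume is conserved exactly. The shipped
YAML mapping follows the FreeSurfer lobe grouping with five lobes per
hemisphere (insula folded into the frontal block to keep that count); it is
data, editable without touching code, and region lists everywhere are
user-supplied rather than hard-coded to any atlas.

## Design planning

`required_timepoints()` inverts the ICC2 formula: the smallest integer
$N > \frac{target}{1-target}\cdot\frac{\sigma^2_E}{\sigma^2_B}$ (strict, with
a 1e-8 guard so that exact boundaries round up; at ICC = .9 and target .9 the
bound is exactly 1 and the answer is 2). `attenuated_correlation()` applies
Spearman's formula $r_{obs} = r_{true}\sqrt{rel_x}\sqrt{rel_y}$, and
`sample_size_for_correlation()` solves the two-sided Fisher-z equation
$\sqrt{n-3}\,\mathrm{atanh}(r) = z_{1-\alpha/2} + z_{power}$, reporting the
integer part of the solution. Floor rather than ceiling is the default
because it reproduces the conventional printed sample-size pairs for
attenuated effect sizes (a `conservative = TRUE` flag rounds up);
`attenuation_power_report()` likewise rounds attenuated correlations to two
decimals before the power step, matching how such effect sizes are reported
and then used.

```{r}
required_timepoints(icc = 0.54)
attenuation_power_report(
  data.frame(label = c("best region", "worst region"),
             rel_region = c(0.90, 0.54)))
```

## The pipeline

`run_pipeline()` sequences simulate/ingest, rescale, optional exploratory
holdout (a withheld participant subset for model tuning, drawn from the run
seed), pooled and grouped maps, map summaries, dispersion, the comparison
grid, rank-order stability, and the design report, writing plain CSV/JSON
plus a manifest. One seed governs everything; reruns are byte-identical. No
quantity is computed in the pipeline layer itself — every number traces to
one exported function above.

## Known limitations

* Two timepoints only: no within-session nesting, no latent growth curves,
  and reliability cannot be separated from true change in rate.
* Regions are fitted independently; no spatial model and no multiplicity
  control across the map (the outputs are estimates, not tests).
* The multigroup optimiser handles the 21-group case comfortably but is dense
  Newton, so very large group counts (hundreds) would want a sparse
  refactor.
* Site and scanner are confounded by design in single-scanner-per-site data;
  the package can group by either but cannot disentangle them.
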