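---
title: "A two-level Bayesian hierarchical Poisson model for PM2.5 constituents and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-level Bayesian hierarchical Poisson model for PM2.5 constituents and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Fine particulate matter (PM2.5) is regulated by total mass concentration,
yet its chemical make-up varies strongly across space, and toxicity may
differ by constituent. **bhpm** implements a two-level Bayesian
hierarchical Poisson analysis designed to ask two questions with multi-site
monthly mortality panels:

* **Main effects** — which constituents (elemental carbon EC, organic
  carbon matter OCM, sulfate SO4, silicon Si, nitrate NO3, sodium Na,
  summarised by long-run average concentrations per site) are associated
  with the level of the mortality rate, controlling for total PM2.5 mass
  and community characteristics?
* **Effect modification** — at which sites is the association between
  previous-year PM2.5 and mortality stronger, and do constituent levels
  explain that spatial variation?

## The model

For monitor location $i$ and month $j$, with $Y_{ij}$ deaths among
$N_{ij}$ persons at risk and $x^*_{ij}$ the previous-1-year-average PM2.5
centred at the location mean $\bar x_i$:

$$Y_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
\log \lambda_{ij} = \log N_{ij} + \alpha_{i0} + \alpha_{i1} x^*_{ij}.$$

The spatially varying (SV) intercept $\alpha_{i0}$ is the log baseline
mortality rate at the site's average exposure; the SV slope $\alpha_{i1}$
is the log rate ratio per 1 µg/m³ of previous-year PM2.5. The second level
regresses both on standardised site covariates — six constituents
$z^*_{ik}$, five community confounders $w^*_{il}$ (median family income,
percent high-school graduates, percent urban, percent white, percent
black), and, in the intercept equation only, the standardised site-average
exposure $\bar x_i$ as a total-mass control:

$$\alpha_{i0} = \beta_0 + \textstyle\sum_k \beta_k z^*_{ik}
  + \sum_l \beta_{6+l} w^*_{il} + \beta_{12}\bar x_i + \varepsilon_{i0},
\qquad
\alpha_{i1} = \gamma_0 + \textstyle\sum_k \gamma_k z^*_{ik}
  + \sum_l \gamma_{6+l} w^*_{il} + \varepsilon_{i1}.$$

Because covariates are standardised, $100(e^{\beta_k}-1)$ is the percent
change in the mortality rate per 1-SD of constituent $k$, and
$100(e^{\gamma_k}-1)$ the percent change in the PM2.5–mortality
association per 1-SD — the reporting scales used throughout.

The errors $\varepsilon_{i0}, \varepsilon_{i1}$ are independent across
equations and either i.i.d. ($\sigma^2 I$) or spatially correlated with an
exponential covariance $\sigma^2 e^{-\phi d} + \tau^2 I$ in inter-monitor
distance $d$ (miles). Crossing four covariate blocks (none, constituents,
confounders, both) with the two error structures gives eight candidate
models, compared by DIC.

## Two-stage estimation

Estimation is deliberately two-stage, the interface isolating this choice
so a joint sampler could be swapped in:

1. **Stage 1** (`fit_location`, `fit_all_locations`): per-location Poisson
   MLE by IRLS with the log population offset, returning
   $(\hat\alpha_{i0}, \hat\alpha_{i1})$ and the inverse observed
   information as a known 2×2 sampling covariance $V_i$. Locations with
   zero total deaths (intercept diverging) or fewer than 6 usable months
   are flagged and excluded from stage 2. No overdispersion term is used:
   the first level is pure Poisson.
2. **Stage 2** (`run_mcmc`): the stage-1 estimates are modelled as
   $\hat\alpha_i \sim N_2(\alpha_i, V_i)$ with $V_i$ fixed, and the level-2
   regressions are sampled by MCMC.

### Sampler design

With independent errors the latent $\alpha_i$ are integrated out
analytically: the chain moves only over $(\beta, \gamma, \sigma_0,
\sigma_1)$, with a joint conjugate normal draw for all coefficients
(per-location 2×2 marginal covariance $V_i + \mathrm{diag}(\sigma_0^2,
\sigma_1^2)$) and an adaptive random-walk Metropolis step on the log error
SDs against the same marginal likelihood. Collapsing matters: conditioning
on latent coefficients creates the classic funnel in which
$\sigma \to 0$ pins the latents and the latents pin $\sigma$; the
collapsed chain reaches a maximum potential-scale-reduction factor of
about 1.1 within 2,000 iterations on 500-site problems.

With spatial errors the latents are kept: the sweep alternates (a) a
multivariate normal draw of each equation's latent coefficient vector,
folding in the cross-equation term of $V_i^{-1}$ through a
pseudo-observation, (b) conjugate coefficient draws under the spatial
covariance, (c) an exact griddy-Gibbs draw of the decay $\phi$ over a
fixed log-spaced grid spanning 40-mile correlations 0.01–0.99, using
eigendecompositions of the correlation matrix precomputed once per grid
point (so a sweep is $O(n^2)$ rather than a fresh $O(n^3)$ factorisation
per proposal, and the decay draw is its exact full conditional with no
tuning), and (d) joint adaptive Metropolis on the sill and nugget SDs.
Step sizes adapt toward ~40% acceptance during burn-in and are frozen
afterwards.

Priors are weakly informative and configurable (`bhpm_priors`): normal(0,
10²) on every regression coefficient, half-normal(0, 1) on the error SDs
(sill and nugget SDs alike), uniform over the decay grid. Defaults are 3
chains of 10,000 iterations with half discarded in `pipeline_config`-style
production runs; the package's own experiments use 2,000–4,000 iterations,
which the PSRF diagnostics support at these problem sizes.

### DIC

`compute_dic` uses the deviance $D(\theta) = -2\log p(\hat\alpha \mid
\theta)$ with the latent coefficients marginalised (per-location bivariate
normal for independent errors; a $2n \times 2n$ Gaussian with the
cross-equation $V_i$ couplings for spatial errors), $pD = \bar D -
D(\bar\theta)$, and the posterior-mean plug-in. Positive scale parameters
(error SDs, nugget, decay) are averaged on the log scale for the plug-in:
an arithmetic mean of a skewed decay posterior is a poor plug-in that
systematically deflates the spatial models' $pD$ and can flip rankings.
Negative $pD$ (a known DIC pathology on null-signal data) produces a
warning, never a silent repair.

## Missing constituents: spatial GP imputation

Constituent monitors are sparser than mass monitors; sites without a
speciation monitor within 6 miles have all six constituents missing.
`fit_spatial_gp` fits, separately per constituent, a constant-mean
Gaussian process with exponential covariance by MCMC (conjugate mean;
adaptive Metropolis on sill and nugget with inverse-gamma(2, sample
variance) priors; exact griddy-Gibbs on the decay grid, with all spectral
quantities cached so a sweep is $O(nG)$). `predict_missing` averages the
kriging conditional mean over hyperparameter draws — single-value
imputation, deliberately mirroring the study design it emulates despite
the acknowledged limitation that it carries no prediction uncertainty into
the regression; predictive SDs are exported so users can do multiple
imputation instead. `cross_validate` reports per-fold Pearson correlation
and RMSE over k = 5 random folds, the diagnostic used to justify
imputation: on calibrated synthetic fields, CV correlations are ~0.65–0.75
and RMSE is ~0.65–0.75 of the sample SD.

A constant GP mean is assumed (no trend surface); the Matérn family is
left as a configuration extension, the exponential being the conventional
default for this class of model.

## The synthetic-data generator

No real mortality or monitoring data ship with the package; every claim is
validated on synthetic studies with known truth (`simulation_truth`,
`simulate_study`). The generator's defaults are the study conditions, not
tuning knobs:

* **Network geometry.** Monitors follow a Thomas-style clustered process
  (40 uniformly placed metropolitan centres, 8-mile Gaussian scatter,
  median nearest-neighbour distance ≈ 4 miles for 518 sites), emulating
  the urban clustering of real networks — under uniform placement over an
  eastern-US-sized region, monitors would sit ~34 miles apart and spatial
  imputation would be information-free, which real networks are not. A
  uniform process is available (`process = "uniform"`), and two misaligned
  networks can share metro centres (`centers =`) to emulate mass vs
  speciation monitor linkage.
* **Constituent fields** are GP draws whose means and SDs match the
  published summary table of the emulated study (e.g. SO4 4.14 ± 0.80
  µg/m³) and whose 40-mile correlations are set to the reported values
  (0.05 EC, 0.20 OCM, 0.21 SO4, 0.19 Si, 0.21 NO3, 0.20 Na). The smooth
  variance fraction is 0.85, reflecting reported short-range (5–10 km)
  correlations of 0.59–0.95.
* **Confounders** are Gaussian with the three reported correlations
  (income–high-school 0.62, white–high-school 0.50, white–black −0.84),
  remaining pairs 0. That matrix is indefinite (smallest eigenvalue
  −0.045); it is projected to the nearest positive-definite correlation
  matrix with a 2.5% eigenvalue floor so draws are correlated but not
  numerically collinear. Proportions are modelled as unbounded Gaussians —
  adequate for a regression covariate, not a claim about their marginal
  law.
* **Exposure** is a site-level long-run mean (13.7 ± 2.13 µg/m³ across
  sites) plus monthly AR(1) deviations with ρ = 0.9 and stationary SD 0.8
  µg/m³. High autocorrelation is structural: previous-year averages of
  adjacent months share 11/12 of their window. The month-to-month law of
  real previous-year averages is not documented in the emulated study;
  this is a declared stand-in.
* **Population at risk** is log-normal across sites (median ≈ 10,000,
  mean ≈ 14,500 per month), matching the emulated study's mean and
  right skew; deaths are Poisson draws from the level-1 model with
  coefficients produced by the level-2 regressions (defaults: three
  constituents with main effects of 1.2–1.4% per SD, two with modifier
  effects of 0.5% per SD, modest confounder effects,
  $\sigma_{\varepsilon 0} = 0.05$, $\sigma_{\varepsilon 1} = 0.004$).
  Usable months per site are uniform on 33–70.

What passing tests on these data do **not** show: robustness to
seasonality in mortality, cause-specific structure, non-Gaussian covariate
tails, monitor-level measurement error, or exposure misalignment between
monitors and the population buffer — none of which the generator emulates.

## Panel construction and linkage rules

* `previous_year_average` uses a 365-calendar-day window ending the day
  before each month's first day, and emits a month only when at least 50%
  of window days have values (both conventions declared here; the emulated
  study states neither an endpoint convention nor a completeness rule, and
  its per-site month counts vary).
* Distances are haversine miles on a sphere of radius 3958.8 miles
  (sub-0.5% error at the 6-mile buffer scale); "within 6 miles" is strict
  inequality everywhere; nearest-monitor ties break to the
  lexicographically smaller id; a planar Euclidean mode supports
  hand-computable test geometry.
* A point centroid inside two buffers is counted in both by default
  (`assign = "all"`), matching the literal aggregation rule;
  `assign = "nearest"` is available.
* Covariate standardisation uses the n−1 SD; the returned constants make
  the transform invertible and exactly reapplicable to new data.

## Validation experiments

The test suite (and `scripts/acceptance.R`, which recomputes headline
quantities from scratch) validates the pipeline end to end; problem sizes
were chosen so the whole suite runs on one CPU in minutes:

* stage-1 MLEs against an exhaustive 2-D grid search (step 10⁻³) on a
  10-site, 40-month panel;
* closed forms: intercept-only MLE $\log(\sum Y / \sum N)$, zero
  coefficients reporting 0.0%, nugget-free kriging interpolating exactly;
* full-pipeline recovery over 50 replicate 241-site, 60-month studies:
  all 25 second-level coefficients within 3 posterior SDs of truth in ≥
  90% of replicates, 95%-interval coverage within [88%, 100%];
* DIC selection: the generating structure (both covariate blocks,
  independent errors) ranked first in ≥ 80% of 25 strong-signal
  replicates; on null data the saturated spatial model does not win by a
  margin > 5 in more than 20%;
* imputation at the 53% masking fraction of a 518-site network: CV RMSE
  below the sample SD for every constituent and mask-recovery correlation
  > 0.5 for all constituents with 40-mile correlation ≥ 0.19;
* bit-for-bit reproducibility of the pipeline under a fixed configuration
  and seed (the run manifest records the configuration hash, seeds, and
  per-stage file digests; cached stages are reused on rerun).

## Known limitations

* Stage 1 is an MLE plug-in: stage-2 inference conditions on $V_i$ as
  known, which understates uncertainty at sites with very few deaths
  (partly mitigated by excluding degenerate sites).
* Single-value imputation propagates no imputation uncertainty into
  stage 2 — by design, to mirror the emulated procedure.
* The spatial error model and GP share one covariance family
  (exponential) and a discretised decay; posteriors for the decay are
  limited to grid resolution (15 points over a wide range by default).
* $\varepsilon_{i0}$ and $\varepsilon_{i1}$ are a priori independent
  across equations; only the stage-1 sampling covariance couples them.
* Age-stratified analyses are supported only by pre-filtering the input
  panel, which is how the emulated design treated them.
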