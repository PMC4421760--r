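# bhpm — Bayesian hierarchical Poisson modelling of PM2.5 constituents and mortality

`bhpm` is an R package for asking which chemical constituents of fine
particulate matter (PM2.5) — elemental carbon, organic carbon matter,
sulfate, silicon, nitrate, sodium — are associated with mortality in
multi-site monthly panels, and which ones strengthen the association
between long-term PM2.5 exposure and mortality. It is written for
environmental epidemiologists and biostatisticians working with networks
of air-quality monitors linked to population death counts.

## The model

For monitor location *i* and month *j*, with *Y*ᵢⱼ deaths among *N*ᵢⱼ
persons at risk and *x\**ᵢⱼ the previous-1-year-average PM2.5 centred at
the location mean:

```
Y_ij ~ Poisson(lambda_ij),   log lambda_ij = log N_ij + alpha_i0 + alpha_i1 * x*_ij

alpha_i0 = beta_0  + sum_k beta_k  z*_ik + sum_l beta_{6+l}  w*_il + beta_12 xbar_i + eps_i0
alpha_i1 = gamma_0 + sum_k gamma_k z*_ik + sum_l gamma_{6+l} w*_il              + eps_i1
```

The spatially varying intercepts `alpha_i0` (log baseline mortality rate)
and slopes `alpha_i1` (log rate ratio per µg/m³) are estimated per
location by Poisson regression with a log population offset, then
regressed on standardised 7-year-average constituent concentrations
`z*`, community confounders `w*` (income, education, urbanicity, racial
composition) and the site-average exposure `xbar` (intercept equation
only, as a total-mass control). Second-level errors are independent or
spatially correlated (exponential covariance in inter-monitor miles);
the eight combinations of covariate blocks and error structures are
compared by DIC. Constituents missing at monitors without a nearby
speciation monitor are imputed by Bayesian Gaussian-process kriging,
validated by 5-fold cross-validation. Coefficients are reported as
`100*(exp(b) - 1)` — percent change per 1-SD of the covariate.

All of this is exercised end to end on synthetic studies with known
truth from the package's calibrated generator (`simulate_study`); no
external data are required. The methods vignette
(`vignettes/constituent-mortality-model.Rmd`) documents the model,
sampler, priors, generator calibration and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic 518-monitor network (run them in order from the repository
root; outputs land in `results/study/`):

```sh
Rscript analysis/01_simulate.R      # networks, linkage, panel, masking
Rscript analysis/02_impute.R        # GP imputation + cross-validation
Rscript analysis/03_stage1.R        # per-location Poisson fits
Rscript analysis/04_stage2_select.R # 8-model DIC selection + final fit
Rscript analysis/05_report.R        # percent-scale effect table
```

Output from a complete run:

```
mass monitors with a speciation monitor within 6 miles: 192 / 518 (median linked distance 3.81 miles)
panel: 26476 location-months over 518 monitors; mean monthly mortality rate 4.53 deaths/1,000 persons
constituents masked at 275 of 518 sites
5-fold CV: correlations 0.66-0.74, RMSE between 0.65 and 0.74 of the sample SD
mask-recovery correlations at 275 imputed sites: ec 0.62, ocm 0.75, so4 0.69, si 0.75, no3 0.75, na 0.75
518 of 518 locations converged
baseline mortality rate (deaths/month/1,000): 4.01 / 4.51 / 5.04 (5th/50th/95th percentile)
DIC ranking (complete-case, n = 243):
  1. both         iid      DIC  -1674.1  pD  27.4
  2. both         spatial  DIC  -1670.0  pD  28.0
  ...
winner: both+iid
all-sites fit: max PSRF 1.012, DIC -3523.7
constituent effects, % per 1-SD (95% posterior interval):
  mortality-rate main effects (intercept equation):
    ec   1.2% (0.7, 1.7)    truth   1.3%
    si   1.2% (0.7, 1.7)    truth   1.4%
    no3  1.4% (0.8, 1.9)    truth   1.2%
  exposure-association modifiers (slope equation):
    so4  0.3% (0.0, 0.5)    truth   0.5%
    na   0.4% (0.2, 0.7)    truth   0.5%
```

Reading this: monitors cluster in metropolitan areas, so 192 of 518 mass
monitors have a speciation monitor within the 6-mile homogeneity radius;
the rest have their constituents imputed by kriging (cross-validation
correlations 0.66–0.74 justify that step). DIC picks the model with both
covariate blocks and spatially independent errors. The three
constituents generated with nonzero main effects (EC, Si, NO3) and the
two generated as modifiers (SO4, Na) are the ones recovered, with 95%
posterior intervals covering the generating truth.

Single functions compose the same way:

```r
library(bhpm)
study  <- simulate_study(simulation_truth(n_locations = 241,
                                          months_per_location = 60, seed = 7))
stage1 <- fit_all_locations(study$panel)
std    <- standardize_covariates(study$covariates)
spec   <- model_spec("both")
fit    <- run_mcmc(stage1, build_design(std$covariates, spec), spec,
                   n_iter = 2000, n_burn = 1000, n_chains = 3, seed = 3)
render_effect_table(fit)
```

## Package layout

| Where | What |
| --- | --- |
| `R/geo_linkage.R` | haversine/planar distances, nearest-within-radius linkage, buffer aggregation |
| `R/panel_builder.R` | previous-year exposure windows, centering, standardisation |
| `R/synthetic_data.R` | calibrated study generator (locations, GP fields, confounders, counts) |
| `R/stage1_poisson.R` | per-location Poisson MLE with sampling covariance |
| `R/stage2_bayes.R` | second-level Gibbs sampler, DIC, eight-model selection, effect scales |
| `R/gp_impute.R` | spatial GP fitting, kriging prediction, cross-validation, imputation |
| `R/reporting.R` | pipeline orchestration, manifests, effect tables |
| `analysis/` | numbered workflow drivers (the worked example above) |
| `tests/testthat/` | unit, property and end-to-end validation suites |
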