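# jsclimate

Bayesian analysis of climate-mediated population dynamics for open
songbird populations, from integrated mark–resight and count data.

A long-term study plot yields two data streams about its breeding
females: capture–resight histories of individually marked birds (with
age at first capture recorded as second-year, after-second-year, or
ambiguous after-hatch-year), and yearly counts of unmarked birds.
`jsclimate` joins the two in a single **data-augmented Jolly–Seber
model** in which per-capita recruitment and age-specific apparent
survival carry logit-linear trends in calendar time, early-breeding
temperature, or annual precipitation:

- recruitment: γ_t = α / (1 + exp(−(β₀^γ + β₁^γ·w_t − β₂^γ·D_t²))),
  with negative density dependence on female density D_t;
- survival over (t−1, t]: logit φ_{j,t−1} = β_{j,0}^φ + β₁^φ·w_{t−1}
  for age class j ∈ {SY, ASY};
- entries: π_t = N_{t−1}·γ_{t−1}/M, driven by the *realized* abundance
  of the augmented state;
- observations: binomial capture of unmarked females, probabilistic
  SY/ASY age assignment, resighting of marked females with a breeding
  propensity that absorbs temporary emigration, and binomial counts of
  unmarked females.

Plot-level climate covariates are predicted from elevation-graded
weather-station series; their prediction SEs enter the model as
measurement error on the latent true covariate. Fitted posteriors feed
a population-viability forecast (demographic stochasticity + parameter
uncertainty + climate-trend uncertainty) and a local extinction risk at
a horizon year.

Inference uses a custom Metropolis-within-Gibbs sampler in C++ with
*exact* per-individual Gibbs updates of the latent entry/death states —
necessary because the realized-abundance entry model makes the entry
distribution depend on the latent state itself, which standard graphical
MCMC engines cannot express. See `vignette("methods")` for the full
model, priors, and validation strategy.

## Worked example

Simulate a 15-year study of an open population on a 100-ha plot with a
known declining recruitment trend (β₁^γ = −0.3) and survival trend
(β₁^φ = −0.35), then refit it and forecast:

```r
library(jsclimate)

cfg <- sim_config(
  T = 15, M = 300, area = 100, EN1 = 35,
  params = model_params(alpha = 1.5, b0_gam = -1.1, b1_gam = -0.3,
                        b2_gam = 2.0, b0_phi_sy = qlogis(0.50),
                        b0_phi_asy = qlogis(0.70), b1_phi = -0.35,
                        b0_cap = qlogis(0.85), k = 0.7, tau = 0.5,
                        p_eta = 0.9),
  seed = 42)
ds <- simulate_dataset(cfg)
ds$data
#> Integrated encounter dataset: plot sim
#>   years: 2002 - 2016 (T = 15)
#>   marked females: 181   augmented to M = 300
#>   unmarked counts: 3 2 3 2 3 2 2 1 3 2 0 0 0 2 1
#>   area: 100 ha;  single-day years: none

fit_weighted_trend(ds$stations, "early_breeding_temperature",
                   weights = "inverse_sd")
#> Climate trend (early_breeding_temperature, all): 0.0453 per yr
#>   (SE 0.0226, 95% CI -0.0004 to 0.0910)

fit <- run_mcmc(ds$data,
                settings = mcmc_settings(chains = 3, iter = 2000,
                                         adapt = 1000, seed = 1))
s <- summarize_posterior(fit)
s[s$parameter %in% c("b1_gam", "b1_phi", "p_eta", "N[15]"), ]
#>  parameter median   lower  upper
#>     b1_gam -0.375 -10.003  8.330
#>     b1_phi -0.361  -0.591 -0.121
#>      p_eta  0.898   0.865  0.926
#>      N[15] 13.000  12.000 16.000   # true final N is 13

fc <- forecast_population(fit, ds$data, horizon = 2040, seed = 1)
extinction_risk(fc)
#> [1] 99.51667
```

The survival trend is recovered with a credible interval well away from
zero; the recruitment trend is recovered but diffuse (a single short
series contains limited information about it, and the recruitment
intercept/bound/density-dependence block is only weakly identified —
see the vignette). Use `assess_convergence(fit)` for split-R̂ and
effective sample sizes per parameter.

A full pipeline driven by a YAML configuration — station filtering,
plot-climate prediction, trend fitting, model fitting per variant,
forecasting, and a JSON report with input checksums — is available via
`run_pipeline()`; see `?run_config`.

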