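# ringwue

Tools for asking how rising atmospheric CO2, climate and stand structure
jointly shape the annual growth and water-use physiology of trees at a
savanna–forest ecotone. The package is built around a two-cohort sampling
design: trees that established before 1895 ("Past", low CO2) are compared
during 1895–1949 with trees that established in 1895–1950 ("Modern",
higher CO2) during 1950–2015, so the two groups are observed at similar
ages and sizes but under different CO2 regimes, in both open savannas and
closed forests.

## The models

**Growth.** Annual log ring width of tree *i* at site *s* in group *c* is

```
log(growth)_isc ~ Normal(g, sigma_p^2)
g = alpha_s + beta_1c * Precip + beta_2c * MaxTemp
            + beta_3c * (MaxTemp x Precip)
            + beta_4c * log(growth)_{t-1} + beta_5c * log(growth)_{t-2}
            + beta_6c * DBH
```

with water-year (Oct–Sep) precipitation, June maximum temperature and DBH
z-scored within each cohort (or cohort-by-structure) group, site random
intercepts `alpha_s ~ N(mu_alpha, sigma2_alpha)`, group random slopes
`beta_kc ~ N(mu_beta_k, sigma2_beta_kc)`, uniform(-2, 2) hyper-means and
inverse-gamma(0.001, 0.001) variances. The posterior is sampled with a
conjugate Gibbs sampler written in the package (`fit_growth_model()`),
with Gelman–Rubin convergence checks, DIC and held-out R²/MSPE/bias.

**Isotopes.** Latewood δ13C is corrected for the Suess effect, converted
to discrimination Δ13C = (δ_atm − δ_plant)/(1 + δ_plant/1000), and to
intrinsic water-use efficiency iWUE = c_a (b − Δ13C) / (1.6 (b − a)) with
a = 4.4‰, b = 27‰. A matching hierarchical model with group baselines
`alpha_c` and slopes on precipitation, temperature and DBH yields
baseline cohort contrasts (`baseline_contrast()`), e.g. the percent
increase in iWUE between past and modern forests.

**Prediction.** `posterior_predict()` projects growth over temperature ×
precipitation grids holding other covariates at group means, with percent
change relative to a reference temperature (26 °C) and modern-vs-past
growth benefit contrasts; `summarize_scenarios()` aggregates climate
scenario tables by period and pathway.

**Synthetic data.** `simulate_study()` generates monthly climate, a
two-cohort tree design, ring-width series (forward from the growth model)
and isotope series (inverted through the discrimination equations) with
known truth, so every stage of the pipeline is testable offline. The
generating coefficients default to the group posterior means reported for
this design.

## Worked example

```r
library(ringwue)

st  <- simulate_study(seed = 1)                         # ~103 trees, 9 sites
obs <- assemble_observations(st$rw, st$meta, st$annual, quiet = TRUE)
obs <- make_groups(obs, "cohort-structure")
obs <- scale_covariates(obs, params = st$truth$growth$scaling)$observations
nrow(obs)
#> [1] 6200

fit <- fit_growth_model(obs, iterations = 4000, burn_in = 2000,
                        thin = 2, chains = 3, seed = 1)
s <- posterior_summary(fit)
s[grepl("beta\\[precip", s$parameter), c("parameter", "mean", "q2.5", "q97.5")]
#>                    parameter  mean     q2.5 q97.5
#>    beta[precip,Past-Savanna] 0.107  0.09332 0.122
#>     beta[precip,Past-Forest] 0.111  0.09180 0.131
#>  beta[precip,Modern-Savanna] 0.015  0.00197 0.029
#>   beta[precip,Modern-Forest] 0.015 -0.00523 0.035
```

Past-cohort growth is strongly precipitation-sensitive (posterior mean
0.107 log-mm per sd of water-year precipitation in past savannas) while
modern-cohort sensitivity is near zero — the generated decline in drought
sensitivity, recovered from the rings. The isotope side:

```r
iso  <- derive_isotopes(st$iso, st$atmosphere)          # Suess, Δ13C, iWUE
io   <- scale_covariates(iso, params = st$truth$isotope$scaling)$observations
ifit <- fit_isotope_model(io, "iwue", seed = 2)
ctr  <- baseline_contrast(ifit, "Modern-Forest", "Past-Forest")
#> Forest baseline iWUE change: +20.8% (95% CI 17.5 to 24.1%)
```

The methods vignette (`vignettes/growth-iwue-methods.Rmd`) documents the
model assumptions, priors, numerical choices and what the synthetic
design does and does not emulate.

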