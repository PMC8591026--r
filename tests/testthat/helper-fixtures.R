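# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# reduced design: 4 sites, 24 trees, small isotope sample — fast to simulate
# and fit, used for unit/property tests
small_config <- function(seed = 42L) {
  sim_config(seed = seed, n_sites = 4L, n_savanna_sites = 2L,
             precip_mean = seq(620, 820, length.out = 4),
             june_tmax_mean = seq(26.5, 24.5, length.out = 4),
             n_past = 12L, n_modern = 12L, n_savanna_trees = 12L,
             iso_sites = c(1L, 3L), iso_trees_per_cohort = 3L,
             iso_years_per_cohort = 6L)
}

small_study <- function() cache_get("small_study", function()
  simulate_study(seed = 42L, config = small_config()))

small_obs <- function() cache_get("small_obs", function() {
  st <- small_study()
  obs <- assemble_observations(st$rw, st$meta, st$annual, quiet = TRUE)
  obs <- make_groups(obs, "cohort-structure")
  scale_covariates(obs, params = st$truth$growth$scaling)$observations
})

small_growth_fit <- function() cache_get("small_growth_fit", function()
  fit_growth_model(small_obs(), iterations = 2000L, burn_in = 1000L,
                   thin = 2L, chains = 3L, seed = 7L))

# full-scale default design, the study conditions; shared by the acceptance
# tests so the expensive fit happens once
default_study <- function() cache_get("default_study", function()
  simulate_study(seed = 1L))

default_obs <- function() cache_get("default_obs", function() {
  st <- default_study()
  obs <- assemble_observations(st$rw, st$meta, st$annual, quiet = TRUE)
  obs <- make_groups(obs, "cohort-structure")
  scale_covariates(obs, params = st$truth$growth$scaling)$observations
})

default_growth_fit <- function() cache_get("default_growth_fit", function()
  fit_growth_model(default_obs(), iterations = 4000L, burn_in = 2000L,
                   thin = 2L, chains = 3L, seed = 1L))

default_iso_obs <- function() cache_get("default_iso_obs", function() {
  st <- default_study()
  d <- derive_isotopes(st$iso, st$atmosphere)
  scale_covariates(d, params = st$truth$isotope$scaling)$observations
})

default_iso_fit <- function() cache_get("default_iso_fit", function()
  fit_isotope_model(default_iso_obs(), "iwue", iterations = 4000L,
                    burn_in = 2000L, thin = 2L, chains = 3L, seed = 2L))

# a degenerate posterior_samples object with draws supplied directly; used
# to test prediction and contrast arithmetic against hand-computable truths
fake_growth_fit <- function(alpha, beta, sigma2_p, n_draws = 1L,
                            spec = growth_model_spec()) {
  K <- length(spec$covariates)
  stopifnot(nrow(beta) == K)
  par_names <- c(paste0("alpha[", names(alpha), "]"),
                 paste0("beta[", outer(spec$covariates, colnames(beta),
                                       paste, sep = ","), "]"),
                 "mu_alpha", paste0("mu_beta[", spec$covariates, "]"),
                 "sigma2_p", "sigma2_alpha",
                 paste0("sigma2_beta[", outer(spec$covariates,
                                              colnames(beta), paste,
                                              sep = ","), "]"))
  v <- c(alpha, as.vector(beta), 0, rep(0, K), sigma2_p, 1,
         rep(1, K * ncol(beta)))
  d <- matrix(rep(v, each = n_draws), n_draws, length(par_names),
              dimnames = list(NULL, par_names))
  structure(list(draws = list(d), par_names = par_names,
                 intercept_labels = names(alpha),
                 group_labels = colnames(beta),
                 slope_names = spec$covariates, model = "growth",
                 spec = spec,
                 settings = list(iterations = n_draws, burn_in = 0L,
                                 thin = 1L, chains = 1L, seed = 0L)),
            class = "posterior_samples")
}

fake_iso_fit <- function(alpha_draws, center = 0, scale = 1) {
  groups <- colnames(alpha_draws)
  par_names <- paste0("alpha[", groups, "]")
  structure(list(draws = list(`colnames<-`(alpha_draws, par_names)),
                 par_names = par_names, intercept_labels = groups,
                 group_labels = groups, slope_names = character(0),
                 model = "isotope_iwue", response = "iwue",
                 response_center = center, response_scale = scale,
                 settings = list()),
            class = "posterior_samples")
}

# small manual observation table with everything the prediction grid needs
toy_pred_obs <- function(group = "Modern-Savanna") {
  data.frame(group = factor(group),
             log_growth = c(0, 0, 0, 0),
             dbh = c(20, 30, 25, 25),
             june_tmax = c(24, 26, 28, 25),
             wy_precip = c(500, 700, 900, 600))
}

toy_scaling <- function(group = "Modern-Savanna") {
  rbind(data.frame(group = group, variable = "wy_precip", mean = 700,
                   sd = 100),
        data.frame(group = group, variable = "june_tmax", mean = 26,
                   sd = 2),
        data.frame(group = group, variable = "dbh", mean = 25, sd = 5))
}
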