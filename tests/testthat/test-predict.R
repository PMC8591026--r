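test_that("a degenerate posterior predicts exp(0) = 1 mm everywhere", {
  spec <- growth_model_spec()
  beta <- matrix(0, 6, 1, dimnames = list(spec$covariates,
                                          "Modern-Savanna"))
  fit <- fake_growth_fit(c(s1 = 0), beta, sigma2_p = 0.01, n_draws = 1)
  grid <- covariate_grid(toy_pred_obs(), tmax = c(24, 26, 28),
                         precip = c(515, 950))
  pred <- posterior_predict(fit, grid, toy_scaling(),
                            include_process_error = FALSE)
  expect_true(all(pred$table$growth_median == 1))
  expect_true(all(pred$mu_draws == 1))
})

test_that("a negative temperature slope gives monotone declining growth", {
  spec <- growth_model_spec(include_interaction = FALSE)
  beta <- matrix(c(0, -0.1, 0, 0, 0), 5, 1,
                 dimnames = list(spec$covariates, "Modern-Savanna"))
  fit <- fake_growth_fit(c(s1 = 0.2), beta, 0.01, n_draws = 3, spec = spec)
  grid <- covariate_grid(toy_pred_obs(), tmax = seq(22, 30, by = 2),
                         precip = 700)
  pred <- posterior_predict(fit, grid, toy_scaling(),
                            include_process_error = FALSE)
  tab <- pred$table[order(pred$table$june_tmax), ]
  expect_true(all(diff(tab$growth_median) < 0))
})

test_that("percent change vs the reference temperature is exact per draw", {
  spec <- growth_model_spec(include_interaction = FALSE)
  beta <- matrix(c(0, -0.2, 0, 0, 0), 5, 1,
                 dimnames = list(spec$covariates, "Modern-Savanna"))
  fit <- fake_growth_fit(c(s1 = 0.1), beta, 0.04, n_draws = 4, spec = spec)
  grid <- covariate_grid(toy_pred_obs(), tmax = c(24, 26, 28),
                         precip = c(515, 950))
  pred <- posterior_predict(fit, grid, toy_scaling())
  ctr <- percent_change_vs_reference(pred, ref_tmax = 26)
  # zero at the reference, in every draw
  cd <- attr(ctr, "contrast_draws")
  ref_pts <- which(ctr$june_tmax == 26)
  expect_true(all(cd[, ref_pts] == 0))
  # brute-force per-draw oracle at every grid point
  for (p in unique(ctr$wy_precip)) {
    pts <- which(ctr$wy_precip == p)
    ref <- pts[ctr$june_tmax[pts] == 26]
    manual <- 100 * (pred$mu_draws[, pts] - pred$mu_draws[, ref]) /
      pred$mu_draws[, ref]
    expect_equal(cd[, pts], manual, tolerance = 1e-10)
  }
  # the -0.2 tmax slope means +2 deg C is a factor exp(-0.2): -18.1%
  pt <- which(ctr$june_tmax == 28 & ctr$wy_precip == 515)
  expect_equal(ctr$pct_change_median[pt], 100 * (exp(-0.2) - 1),
               tolerance = 1e-8)
  expect_error(percent_change_vs_reference(pred, ref_tmax = 25),
               "not present")
})

test_that("process error widens predictive intervals but not contrasts", {
  fit <- small_growth_fit()
  obs <- small_obs()
  grid <- covariate_grid(obs, tmax = c(24, 26), precip = c(515, 950),
                         groups = "Modern-Savanna")
  sc <- small_study()$truth$growth$scaling
  with_err <- posterior_predict(fit, grid, sc, include_process_error = TRUE,
                                seed = 3)
  without <- posterior_predict(fit, grid, sc, include_process_error = FALSE,
                               seed = 3)
  w1 <- with_err$table$growth_hi - with_err$table$growth_lo
  w0 <- without$table$growth_hi - without$table$growth_lo
  expect_true(all(w0 < w1))
  # the process-error-free component is identical
  expect_identical(with_err$mu_draws, without$mu_draws)
})

test_that("posterior-predictive mean matches the lognormal closed form", {
  spec <- growth_model_spec()
  beta <- matrix(0, 6, 1, dimnames = list(spec$covariates,
                                          "Modern-Savanna"))
  s2 <- 0.25
  fit <- fake_growth_fit(c(s1 = 0.3), beta, s2, n_draws = 40000)
  grid <- covariate_grid(toy_pred_obs(), tmax = 26, precip = 700)
  pred <- posterior_predict(fit, grid, toy_scaling(), seed = 10)
  mc <- mean(pred$pred_draws[, 1])
  closed <- exp(0.3 + s2 / 2)
  se <- stats::sd(pred$pred_draws[, 1]) / sqrt(nrow(pred$pred_draws))
  expect_lt(abs(mc - closed), 3 * se)
})

test_that("cohort benefit contrasts are exact on constructed posteriors", {
  spec <- growth_model_spec()
  mk <- function(group, a) {
    beta <- matrix(0, 6, 1, dimnames = list(spec$covariates, group))
    fit <- fake_growth_fit(c(s1 = a), beta, 0.01, n_draws = 5)
    grid <- covariate_grid(toy_pred_obs(group), tmax = c(24, 26),
                           precip = c(515, 950))
    sc <- toy_scaling(group)
    posterior_predict(fit, grid, sc, include_process_error = FALSE)
  }
  pm <- mk("Modern-Savanna", log(1.2))
  pp <- mk("Past-Savanna", 0)
  ben <- cohort_benefit(pm, pp, "Modern-Savanna", "Past-Savanna")
  expect_equal(ben$benefit_mean, rep(20, 4), tolerance = 1e-10)
  same <- cohort_benefit(pp, pp, "Past-Savanna", "Past-Savanna")
  expect_true(all(same$benefit_mean == 0))
})

test_that("extrapolation beyond the historical range is flagged", {
  fit <- small_growth_fit()
  obs <- small_obs()
  grid <- covariate_grid(obs, tmax = c(26, 45), precip = 700,
                         groups = "Modern-Savanna")
  pred <- posterior_predict(fit, grid, small_study()$truth$growth$scaling)
  tab <- pred$table
  expect_true(tab$extrapolated[tab$june_tmax == 45])
  expect_false(tab$extrapolated[tab$june_tmax == 26])
})

test_that("scenario summaries respect periods and the 2075 convention", {
  scen <- expand.grid(model = c("m1", "m2"), rcp = "4.5",
                      year = c(2030, 2074, 2075, 2080))
  scen$june_tmax <- 30
  scen$annual_precip <- 600
  out <- summarize_scenarios(scen)
  expect_equal(out$tmax_mean, rep(30, nrow(out)))
  expect_equal(out$tmax_min, out$tmax_max)
  # 2075 belongs to the later period only
  expect_equal(out$n[out$period == "2050-2075"], 2L)
  expect_equal(out$n[out$period == "2075-2099"], 4L)

  # hand-computed means on a toy two-model table
  scen2 <- data.frame(model = c("a", "b"), rcp = "8.5", year = 2030,
                      june_tmax = c(28, 32), annual_precip = c(500, 700))
  out2 <- summarize_scenarios(scen2, periods = list(c(2025, 2049)),
                              hist_tmax_range = c(21, 31))
  expect_equal(out2$tmax_mean, 30)
  expect_equal(out2$precip_mean, 600)
  expect_true(out2$tmax_outside_hist)
})
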