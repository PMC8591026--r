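one_obs <- function(precip = 1, tmax = 1, inter = precip * tmax, lag1 = 0.4,
                    lag2 = 0.1, dbh = 2, site = "s1",
                    group = "Past-Savanna", y = 0.5) {
  data.frame(site_id = site, group = factor(group), log_growth = y,
             precip_scaled = precip, tmax_scaled = tmax,
             interaction = inter, lag1_log_growth = lag1,
             lag2_log_growth = lag2, dbh_scaled = dbh)
}

test_that("linear predictor reproduces hand-computed values", {
  spec <- growth_model_spec()
  beta <- matrix(c(0.1, -0.07, 0.06, 0.5, 0.2, 0.05), 6, 1,
                 dimnames = list(spec$covariates, "Past-Savanna"))
  obs <- one_obs()
  g <- linear_predictor(c(s1 = 0.2), beta, obs, spec)
  expect_equal(g, 0.2 + 0.1 - 0.07 + 0.06 + 0.5 * 0.4 + 0.2 * 0.1 +
                 0.05 * 2)
  expect_equal(g, 0.61)

  # zero slopes: predictor is the site intercept
  beta0 <- beta * 0
  expect_equal(linear_predictor(c(s1 = 0.5), beta0, obs, spec), 0.5)

  # unknown site or group is an error, not NA
  expect_error(linear_predictor(c(s2 = 0.5), beta0, obs, spec),
               "unknown site")
  expect_error(linear_predictor(c(s1 = 0.5),
                                `colnames<-`(beta0, "Modern-Forest"),
                                obs, spec), "unknown group")
})

test_that("log likelihood matches an independent density formula", {
  spec <- growth_model_spec()
  beta <- matrix(0, 6, 1, dimnames = list(spec$covariates, "Past-Savanna"))
  # at the mean with variance 1/(2*pi), the log density is exactly 0
  o1 <- one_obs(precip = 0, tmax = 0, inter = 0, lag1 = 0, lag2 = 0,
                dbh = 0, y = 0.3)
  expect_equal(growth_loglik(c(s1 = 0.3), beta, 1 / (2 * pi), o1, spec), 0)

  # ten random rows against the closed-form normal density sum
  set.seed(5)
  obs10 <- do.call(rbind, lapply(1:10, function(i)
    one_obs(precip = rnorm(1), tmax = rnorm(1), lag1 = rnorm(1),
            lag2 = rnorm(1), dbh = rnorm(1), y = rnorm(1))))
  obs10$interaction <- obs10$precip_scaled * obs10$tmax_scaled
  b <- matrix(rnorm(6, 0, 0.2), 6, 1,
              dimnames = list(spec$covariates, "Past-Savanna"))
  alpha <- c(s1 = 0.2)
  s2 <- 0.31
  g <- alpha + as.matrix(obs10[c("precip_scaled", "tmax_scaled",
                                 "interaction", "lag1_log_growth",
                                 "lag2_log_growth", "dbh_scaled")]) %*% b
  manual <- sum(-0.5 * log(2 * pi * s2) -
                  (obs10$log_growth - g)^2 / (2 * s2))
  expect_equal(growth_loglik(alpha, b, s2, obs10, spec), manual,
               tolerance = 1e-10)
  # doubling the data doubles the log likelihood
  expect_equal(growth_loglik(alpha, b, s2, rbind(obs10, obs10), spec),
               2 * manual, tolerance = 1e-10)
})

test_that("sampler matches the conjugate closed form on a one-group model", {
  # covariate-free, single site, fixed hyper-parameters: alpha | y is exactly
  # N((sum(y)/s2 + m0/s02) / p, 1/p) with p = n/s2 + 1/s02
  set.seed(21)
  n <- 60
  y <- rnorm(n, 1.2, 0.5)
  s2 <- 0.25; m0 <- 0; s02 <- 4
  fit <- ringwue:::hbm_gibbs(y, matrix(numeric(0), n, 0),
                             intercept_index = rep("g", n),
                             slope_group = rep("g", n),
                             iterations = 6000, burn_in = 1000, thin = 1,
                             chains = 2, seed = 4,
                             fixed = list(sigma2_p = s2, mu_alpha = m0,
                                          sigma2_alpha = s02))
  prec <- n / s2 + 1 / s02
  post_mean <- (sum(y) / s2 + m0 / s02) / prec
  post_sd <- sqrt(1 / prec)
  a <- as.matrix(fit)[, "alpha[g]"]
  mcse <- post_sd / sqrt(length(a))
  expect_lt(abs(mean(a) - post_mean), 3 * mcse)
  expect_lt(abs(stats::sd(a) - post_sd), 3 * post_sd / sqrt(length(a)))
})

test_that("chains are bit-identical under the same seed", {
  obs <- small_obs()
  f1 <- fit_growth_model(obs, iterations = 300, burn_in = 100, thin = 2,
                         chains = 2, seed = 77)
  f2 <- fit_growth_model(obs, iterations = 300, burn_in = 100, thin = 2,
                         chains = 2, seed = 77)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_growth_model(obs, iterations = 300, burn_in = 100, thin = 2,
                         chains = 2, seed = 78)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("prior support is respected in every retained draw", {
  m <- as.matrix(small_growth_fit())
  mu_cols <- grep("^mu_", colnames(m))
  expect_true(all(m[, mu_cols] >= -2 & m[, mu_cols] <= 2))
  var_cols <- grep("^sigma2", colnames(m))
  expect_true(all(m[, var_cols] > 0))
})

test_that("a single chain is refused", {
  expect_error(fit_growth_model(small_obs(), chains = 1),
               "at least 2 chains")
})

test_that("Gelman-Rubin matches an independent implementation", {
  # identical chains: no between-chain variance
  d <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(max(abs(gelman_rubin(list(d, d, d)) - 1)), 0.01)

  # disjoint supports: far above the 1.1 convergence threshold
  d0 <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "a"))
  d10 <- d0 + 10
  expect_gt(gelman_rubin(list(d0, d10))[["a"]], 3)

  # random three-chain fixture against the textbook formula
  set.seed(8)
  chains <- lapply(1:3, function(i)
    matrix(rnorm(150, i * 0.1), 50, 3,
           dimnames = list(NULL, c("p1", "p2", "p3"))))
  ref <- sapply(1:3, function(p) {
    draws <- sapply(chains, function(ch) ch[, p])   # n x m
    n <- nrow(draws); m <- ncol(draws)
    W <- mean(apply(draws, 2, var))
    B <- n * var(colMeans(draws))
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  expect_equal(unname(gelman_rubin(chains)), ref, tolerance = 1e-8)

  expect_error(gelman_rubin(list(d0)), "2 chains")
})

test_that("held-out metrics behave at their defining limits", {
  obs <- small_obs()
  sp <- train_test_split(obs, frac = 0.75, seed = 2)
  fit <- small_growth_fit()
  met <- model_metrics(fit, sp$train, sp$test)
  expect_true(met$r2 > 0.5 && met$r2 < 1)
  expect_gt(met$mspe, 0)
  expect_lt(abs(met$bias), 0.1)
  expect_equal(met$dic, met$mean_deviance + met$p_d)
  expect_warning(model_metrics(fit, sp$train, NULL), "held-out")
})

test_that("DIC components match a hand-computed deviance on a fixed model", {
  # with all parameters fixed, every draw has the same deviance, so
  # mean deviance equals the deviance at the posterior mean and pD = 0
  set.seed(13)
  n <- 12
  y <- rnorm(n, 0.5, 0.4)
  fit <- ringwue:::hbm_gibbs(y, matrix(numeric(0), n, 0),
                             intercept_index = rep("g", n),
                             slope_group = rep("g", n),
                             iterations = 200, burn_in = 100, thin = 1,
                             chains = 2, seed = 4,
                             fixed = list(sigma2_p = 0.16))
  fit$model <- "growth"
  fit$spec <- growth_model_spec(include_interaction = FALSE)
  fit$spec$covariates <- character(0)
  fit$slope_names <- character(0)
  train <- data.frame(site_id = "g", group = factor("g"), log_growth = y)
  met <- suppressWarnings(model_metrics(fit, train, NULL))
  a_bar <- mean(as.matrix(fit)[, "alpha[g]"])
  d_hat <- -2 * sum(dnorm(y, a_bar, 0.4, log = TRUE))
  expect_equal(met$dic, 2 * met$mean_deviance - d_hat, tolerance = 1e-6)
  expect_gt(met$p_d, 0)        # alpha still varies across draws
  expect_lt(met$p_d, 2)        # about one effective parameter
})

test_that("model comparison prefers structure groups when they differ", {
  st <- small_study()
  obs <- assemble_observations(st$rw, st$meta, st$annual, quiet = TRUE)
  sp <- train_test_split(obs, frac = 0.75, seed = 3)
  cmp <- compare_models(sp$train, sp$test,
                        list(growth_model_spec("cohort"),
                             growth_model_spec("cohort-structure")),
                        iterations = 1500, burn_in = 750, thin = 2,
                        chains = 2, seed = 5)
  expect_equal(nrow(cmp), 2L)
  expect_false(any(cmp$failed))
  expect_equal(sum(cmp$best_dic), 1L)
  # the generating slopes differ across structures, so the four-group model
  # should predict held-out growth at least as well
  expect_lt(cmp$mspe[2], cmp$mspe[1] * 1.05)
})

test_that("posterior means track every generating slope at the default scale", {
  s <- posterior_summary(default_growth_fit())
  truth <- default_study()$truth$growth
  z <- unlist(lapply(colnames(truth$beta), function(g)
    sapply(rownames(truth$beta), function(k) {
      row <- s[s$parameter == paste0("beta[", k, ",", g, "]"), ]
      (row$mean - truth$beta[k, g]) / row$sd
    })))
  # 24 standardized recovery errors: individually a 2-sd miss happens about
  # once in twenty, so require the joint pattern expected of calibrated
  # estimates rather than a zero-miss rule
  expect_true(all(abs(z) < 3))
  expect_gte(sum(abs(z) < 2), 22L)
})

test_that("posterior matches an independent rjags fit of the same model", {
  skip_if_not_installed("rjags")
  obs <- small_obs()
  spec <- growth_model_spec()
  fit <- small_growth_fit()
  X <- ringwue:::growth_design(obs, spec)
  dat <- list(y = obs$log_growth, X = X, n = nrow(X), K = ncol(X),
              site = as.integer(factor(obs$site_id)),
              grp = as.integer(obs$group),
              J = length(unique(obs$site_id)), C = nlevels(obs$group))
  model_str <- "model {
    for (i in 1:n) {
      mu[i] <- alpha[site[i]] + inprod(X[i, ], beta[, grp[i]])
      y[i] ~ dnorm(mu[i], tau_p)
    }
    for (j in 1:J) { alpha[j] ~ dnorm(mu_alpha, tau_alpha) }
    for (k in 1:K) { for (c in 1:C) { beta[k, c] ~ dnorm(mu_beta[k], tau_beta[k, c])
        tau_beta[k, c] ~ dgamma(0.001, 0.001) } }
    for (k in 1:K) { mu_beta[k] ~ dunif(-2, 2) }
    mu_alpha ~ dunif(-2, 2)
    tau_p ~ dgamma(0.001, 0.001)
    tau_alpha ~ dgamma(0.001, 0.001)
  }"
  set.seed(1)
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          n.chains = 2, quiet = TRUE)
  stats::update(jm, 1000, progress.bar = "none")
  js <- rjags::coda.samples(jm, "beta", n.iter = 2000,
                            progress.bar = "none")
  jm_mat <- do.call(rbind, lapply(js, as.matrix))
  own <- posterior_summary(fit)
  for (k in seq_along(spec$covariates)) {
    for (c in seq_len(nlevels(obs$group))) {
      own_row <- own[own$parameter == paste0("beta[", spec$covariates[k],
                                             ",", levels(obs$group)[c], "]"), ]
      jag <- jm_mat[, paste0("beta[", k, ",", c, "]")]
      # agreement within combined posterior uncertainty
      tol <- 3 * sqrt(own_row$sd^2 / 10 + stats::var(jag) / 10) + 0.01
      expect_lt(abs(own_row$mean - mean(jag)), tol)
    }
  }
})
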