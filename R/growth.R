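#' Specify a hierarchical growth model
#'
#' The annual log ring width of tree `i` at site `s` in group `c` is
#' modelled as
#' \deqn{g = \alpha_s + \beta_{1c} Precip + \beta_{2c} MaxTemp +
#'   \beta_{3c} (MaxTemp \times Precip) + \beta_{4c} lag_1 +
#'   \beta_{5c} lag_2 + \beta_{6c} DBH}
#' with \eqn{\log(growth) \sim N(g, \sigma_p^2)}. Groups are either the two
#' establishment cohorts or the four cohort-by-stand-structure classes;
#' slopes vary by group around shared hyper-means, and site intercepts are
#' shared across cohorts within a site.
#'
#' @param grouping `"cohort-structure"` (4 groups) or `"cohort"` (2 groups).
#' @param include_interaction Include the temperature-by-precipitation
#'   product term.
#' @return A `growth_spec` list.
#' @export
growth_model_spec <- function(grouping = c("cohort-structure", "cohort"),
                              include_interaction = TRUE) {
  grouping <- match.arg(grouping)
  covariates <- c("precip", "tmax",
                  if (include_interaction) "interaction",
                  "lag1", "lag2", "dbh")
  structure(list(grouping = grouping,
                 include_interaction = include_interaction,
                 covariates = covariates),
            class = "growth_spec")
}

growth_design_cols <- c(precip = "precip_scaled", tmax = "tmax_scaled",
                        interaction = "interaction",
                        lag1 = "lag1_log_growth", lag2 = "lag2_log_growth",
                        dbh = "dbh_scaled")

growth_design <- function(obs, spec) {
  cols <- growth_design_cols[spec$covariates]
  miss <- setdiff(unname(cols), names(obs))
  if (length(miss))
    stop("observations lack columns ", paste(miss, collapse = ", "),
         "; run make_groups() and scale_covariates() first")
  X <- as.matrix(obs[unname(cols)])
  colnames(X) <- names(cols)
  X
}

#' Evaluate the growth-model linear predictor
#'
#' @param alpha Named vector of site intercepts (log-mm scale).
#' @param beta Matrix of slopes, covariates in rows (named as in
#'   `spec$covariates`), groups in columns (named with group labels).
#' @param obs Observation table with scaled covariates, `site_id`, `group`.
#' @param spec A [growth_model_spec()].
#' @return Numeric vector `g`, one value per observation (log mm).
#' @export
linear_predictor <- function(alpha, beta, obs, spec = growth_model_spec()) {
  if (!all(obs$site_id %in% names(alpha)))
    stop("unknown site in observations: ",
         paste(setdiff(unique(obs$site_id), names(alpha)), collapse = ", "))
  if (is.null(beta) || length(spec$covariates) == 0L)
    return(as.numeric(alpha[obs$site_id]))
  if (!all(as.character(obs$group) %in% colnames(beta)))
    stop("unknown group in observations: ",
         paste(setdiff(unique(as.character(obs$group)), colnames(beta)),
               collapse = ", "))
  X <- growth_design(obs, spec)
  b_rows <- t(beta)[as.character(obs$group), spec$covariates, drop = FALSE]
  as.numeric(alpha[obs$site_id] + rowSums(X * b_rows))
}

#' Growth-model log likelihood
#'
#' Sum over observations of the normal log density of observed log growth
#' at the linear predictor, with process variance `sigma2_p`.
#'
#' @inheritParams linear_predictor
#' @param sigma2_p Process variance (> 0).
#' @return Scalar log likelihood.
#' @export
growth_loglik <- function(alpha, beta, sigma2_p, obs,
                          spec = growth_model_spec()) {
  stopifnot(sigma2_p > 0)
  g <- linear_predictor(alpha, beta, obs, spec)
  ll <- stats::dnorm(obs$log_growth, g, sqrt(sigma2_p), log = TRUE)
  if (any(!is.finite(ll)))
    stop("non-finite log likelihood at row(s) ",
         paste(utils::head(which(!is.finite(ll)), 5L), collapse = ", "))
  sum(ll)
}

#' Fit the hierarchical growth model by conjugate Gibbs sampling
#'
#' Priors follow the model definition: site intercepts
#' \eqn{\alpha_s \sim N(\mu_\alpha, \sigma^2_\alpha)}, group slopes
#' \eqn{\beta_{kc} \sim N(\mu_{\beta k}, \sigma^2_{\beta kc})}, hyper-means
#' uniform on \[-2, 2\], and all variances inverse-gamma(0.001, 0.001).
#' All full conditionals are conjugate; hyper-means are drawn from their
#' normal full conditionals truncated to the uniform support. Convergence is
#' checked with the Gelman-Rubin statistic; a fit whose largest rhat exceeds
#' `rhat_threshold` is returned with a prominent warning and
#' `attr(, "converged") = FALSE`, never silently.
#'
#' @param obs Scaled, grouped observation table (see [make_groups()] and
#'   [scale_covariates()]).
#' @param spec A [growth_model_spec()]; its `grouping` must match the
#'   grouping used to build `obs$group`.
#' @param iterations,burn_in,thin,chains,seed MCMC settings. At least two
#'   chains are required for the convergence diagnostic.
#' @param rhat_threshold Convergence threshold (default 1.1).
#' @return A `posterior_samples` object with parameters `alpha[site]`,
#'   `beta[covariate,group]`, `mu_alpha`, `mu_beta[covariate]`, `sigma2_p`,
#'   `sigma2_alpha` and `sigma2_beta[covariate,group]`.
#' @export
fit_growth_model <- function(obs, spec = growth_model_spec(),
                             iterations = 4000L, burn_in = 2000L, thin = 2L,
                             chains = 3L, seed = 1L, rhat_threshold = 1.1) {
  if (chains < 2L)
    stop("at least 2 chains are required for the Gelman-Rubin diagnostic")
  if (is.null(obs$group)) stop("obs must carry a 'group' column")
  X <- growth_design(obs, spec)
  fit <- hbm_gibbs(obs$log_growth, X, intercept_index = obs$site_id,
                   slope_group = obs$group, iterations = iterations,
                   burn_in = burn_in, thin = thin, chains = chains,
                   seed = seed, slope_names = spec$covariates)
  fit$model <- "growth"
  fit$spec <- spec
  rhat <- gelman_rubin(fit)
  attr(fit, "max_rhat") <- max(rhat)
  attr(fit, "converged") <- max(rhat) <= rhat_threshold
  if (!attr(fit, "converged"))
    warning("growth model did not reach convergence: max rhat = ",
            format(max(rhat), digits = 4), " (threshold ", rhat_threshold,
            "); inspect chains before use", call. = FALSE)
  fit
}

# posterior mean parameters arranged as (alpha vector, beta matrix, sigma2_p)
posterior_mean_params <- function(fit) {
  m <- colMeans(as.matrix(fit))
  extract_params(fit, m)
}

# arrange one named parameter vector into alpha / beta / sigma2_p
extract_params <- function(fit, v) {
  alpha <- v[paste0("alpha[", fit$intercept_labels, "]")]
  names(alpha) <- fit$intercept_labels
  K <- length(fit$slope_names)
  beta <- NULL
  if (K > 0) {
    beta <- matrix(v[paste0("beta[", outer(fit$slope_names, fit$group_labels,
                                           paste, sep = ","), "]")],
                   K, length(fit$group_labels),
                   dimnames = list(fit$slope_names, fit$group_labels))
  }
  list(alpha = alpha, beta = beta, sigma2_p = unname(v["sigma2_p"]))
}

#' Fit diagnostics and held-out predictive metrics
#'
#' Computes the Deviance Information Criterion on the training rows
#' (DIC = mean deviance + pD, with the Spiegelhalter effective parameter
#' count pD = mean deviance minus deviance at the posterior mean) and, on
#' held-out rows, the R-squared of posterior-mean predicted versus observed
#' log growth (1 - SSE/SST), the mean squared prediction error and the bias
#' (mean of predicted minus observed).
#'
#' @param fit A fitted growth model.
#' @param train Training observation table used for the fit.
#' @param test Held-out observation table (disjoint from `train`); may be
#'   `NULL`, in which case held-out metrics are `NA` and flagged.
#' @return List with `dic`, `p_d`, `mean_deviance`, `r2`, `mspe`, `bias`,
#'   and `max_rhat`.
#' @export
model_metrics <- function(fit, train, test = NULL) {
  spec <- fit$spec
  M <- as.matrix(fit)
  dev <- apply(M, 1, function(v) {
    p <- extract_params(fit, v)
    -2 * growth_loglik(p$alpha, p$beta, p$sigma2_p, train, spec)
  })
  pm <- posterior_mean_params(fit)
  d_hat <- -2 * growth_loglik(pm$alpha, pm$beta, pm$sigma2_p, train, spec)
  d_bar <- mean(dev)
  p_d <- d_bar - d_hat
  dic <- d_bar + p_d

  r2 <- mspe <- bias <- NA_real_
  if (!is.null(test) && nrow(test) > 0) {
    pred <- linear_predictor(pm$alpha, pm$beta, test, spec)
    err <- pred - test$log_growth
    mspe <- mean(err^2)
    bias <- mean(err)
    sst <- sum((test$log_growth - mean(test$log_growth))^2)
    r2 <- 1 - sum(err^2) / sst
  } else {
    warning("empty held-out set: R2/MSPE/bias undefined")
  }
  list(dic = dic, p_d = p_d, mean_deviance = d_bar, r2 = r2, mspe = mspe,
       bias = bias, max_rhat = attr(fit, "max_rhat"))
}

#' Fit and compare several model specifications
#'
#' Fits each specification on the same training rows and evaluates each on
#' the same held-out rows; the lowest-DIC specification is flagged. A failed
#' fit marks its row without affecting the others.
#'
#' @param train,test Shared observation tables; `train` must carry group
#'   columns for every grouping used (rebuilt internally per spec).
#' @param specs List of [growth_model_spec()] objects.
#' @param ... MCMC settings passed to [fit_growth_model()].
#' @return Data frame with one row per spec (grouping, interaction flag,
#'   DIC, R2, MSPE, bias, max rhat, `best_dic` flag, `failed` flag), with
#'   the fitted models in `attr(, "fits")`.
#' @export
compare_models <- function(train, test, specs, ...) {
  rows <- list(); fits <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    sc <- scale_covariates(make_groups(train, spec$grouping))
    tr <- sc$observations
    te <- if (!is.null(test) && nrow(test))
      scale_covariates(make_groups(test, spec$grouping),
                       params = sc$scaling)$observations else NULL
    res <- tryCatch({
      fit <- fit_growth_model(tr, spec, ...)
      met <- model_metrics(fit, tr, te)
      fits[[i]] <- fit
      data.frame(grouping = spec$grouping,
                 interaction = spec$include_interaction,
                 dic = met$dic, p_d = met$p_d, r2 = met$r2,
                 mspe = met$mspe, bias = met$bias,
                 max_rhat = met$max_rhat, failed = FALSE)
    }, error = function(e) {
      warning("fit failed for spec ", i, ": ", conditionMessage(e))
      data.frame(grouping = spec$grouping,
                 interaction = spec$include_interaction,
                 dic = NA_real_, p_d = NA_real_, r2 = NA_real_,
                 mspe = NA_real_, bias = NA_real_, max_rhat = NA_real_,
                 failed = TRUE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  out$best_dic <- !is.na(out$dic) & out$dic == min(out$dic, na.rm = TRUE)
  attr(out, "fits") <- fits
  out
}

#' Write posterior draws as a long-format CSV
#'
#' One row per (chain, iteration, parameter), suitable for external
#' diagnostics tooling.
#'
#' @param fit A `posterior_samples` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  rows <- lapply(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]]
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(d)), times = ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
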