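# Conjugate Gibbs sampler for the shared hierarchical normal model
#
#   y_i = alpha_{j(i)} + x_i' beta_{c(i)} + eps_i,   eps ~ N(0, sigma2_p)
#   alpha_j   ~ N(mu_alpha, sigma2_alpha)
#   beta_{k,c}~ N(mu_beta_k, sigma2_beta_{k,c})
#   mu_*      ~ Uniform(mu_range)
#   variances ~ inverse-gamma(ig_shape, ig_rate)
#
# The growth model uses j = site, c = cohort(-structure) group; the isotope
# model uses j = c = group. All updates are conjugate; the hyper-means are
# drawn from their normal full conditionals truncated to mu_range by the
# inverse-CDF method. Chains run sequentially off a single seeded stream
# with chain-specific random initial values.

rinvgamma1 <- function(n, shape, rate) 1 / stats::rgamma(n, shape, rate = rate)

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  # full conditional mass can sit almost entirely outside the support bounds;
  # clamp to the nearer bound in that degenerate case
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)
}

hbm_gibbs <- function(y, X, intercept_index, slope_group,
                      iterations = 4000L, burn_in = iterations %/% 2L,
                      thin = 2L, chains = 3L, seed = 1L,
                      mu_range = c(-2, 2), ig_shape = 0.001, ig_rate = 0.001,
                      fixed = list(), slope_names = colnames(X)) {
  stopifnot(is.numeric(y), length(y) == nrow(X), chains >= 1L,
            burn_in < iterations, thin >= 1L)
  n <- length(y)
  j_fac <- droplevels(as.factor(intercept_index))
  c_fac <- droplevels(as.factor(slope_group))
  J <- nlevels(j_fac); C <- nlevels(c_fac)
  K <- ncol(X)
  if (K > 0 && is.null(slope_names)) slope_names <- paste0("x", seq_len(K))
  jlab <- levels(j_fac); clab <- levels(c_fac)
  ji <- as.integer(j_fac); ci <- as.integer(c_fac)
  tab_c <- lapply(seq_len(C), function(c) which(ci == c))
  if (any(vapply(tab_c, length, 1L) < 2L))
    stop("each slope group needs at least 2 observations")
  n_j <- tabulate(ji, J)
  Xc <- lapply(tab_c, function(idx) X[idx, , drop = FALSE])
  XtXc <- lapply(Xc, crossprod)
  yc <- lapply(tab_c, function(idx) y[idx])
  jc <- lapply(tab_c, function(idx) ji[idx])

  par_names <- c(paste0("alpha[", jlab, "]"),
                 if (K > 0) paste0("beta[", outer(slope_names, clab, paste,
                                                  sep = ","), "]"),
                 "mu_alpha",
                 if (K > 0) paste0("mu_beta[", slope_names, "]"),
                 "sigma2_p", "sigma2_alpha",
                 if (K > 0) paste0("sigma2_beta[", outer(slope_names, clab,
                                                         paste, sep = ","), "]"))
  P <- length(par_names)
  n_keep <- (iterations - burn_in) %/% thin

  set.seed(as.integer(seed))
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    # overdispersed chain-specific starting values
    alpha <- mean(y) + stats::runif(J, -0.5, 0.5)
    beta <- matrix(stats::runif(K * C, -0.5, 0.5), K, C)
    mu_alpha <- fixed$mu_alpha %||% 0
    mu_beta <- rep(0, K)
    s2p <- fixed$sigma2_p %||% stats::var(y) %||% 1
    s2a <- fixed$sigma2_alpha %||% 1
    s2b <- matrix(1, K, C)
    out <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, par_names))
    kept <- 0L

    Xb <- numeric(n)
    for (c in seq_len(C))
      if (K > 0) Xb[tab_c[[c]]] <- Xc[[c]] %*% beta[, c]

    for (t in seq_len(iterations)) {
      # site / group intercepts
      r <- y - Xb
      S <- rowsum(r, ji, reorder = TRUE)[, 1L]
      prec <- n_j / s2p + 1 / s2a
      mn <- (S / s2p + mu_alpha / s2a) / prec
      alpha <- stats::rnorm(J, mn, sqrt(1 / prec))

      # slope blocks, one multivariate normal draw per group
      if (K > 0) {
        for (c in seq_len(C)) {
          rc <- yc[[c]] - alpha[jc[[c]]]
          A <- XtXc[[c]] / s2p + diag(1 / s2b[, c], K)
          b <- crossprod(Xc[[c]], rc) / s2p + mu_beta / s2b[, c]
          U <- chol(A)
          m <- backsolve(U, forwardsolve(t(U), b))
          beta[, c] <- m + backsolve(U, stats::rnorm(K))
          Xb[tab_c[[c]]] <- Xc[[c]] %*% beta[, c]
        }
      }

      # hyper-means, truncated to the uniform prior support
      if (is.null(fixed$mu_alpha))
        mu_alpha <- rtruncnorm1(1, mean(alpha), sqrt(s2a / J),
                                mu_range[1], mu_range[2])
      if (K > 0) {
        pr_k <- rowSums(1 / s2b)
        mn_k <- rowSums(beta / s2b) / pr_k
        mu_beta <- rtruncnorm1(K, mn_k, sqrt(1 / pr_k),
                               mu_range[1], mu_range[2])
      }

      # variances
      e <- y - alpha[ji] - Xb
      if (is.null(fixed$sigma2_p))
        s2p <- rinvgamma1(1, ig_shape + n / 2, ig_rate + sum(e^2) / 2)
      if (is.null(fixed$sigma2_alpha))
        s2a <- rinvgamma1(1, ig_shape + J / 2,
                          ig_rate + sum((alpha - mu_alpha)^2) / 2)
      if (K > 0) {
        dev2 <- (beta - mu_beta)^2
        s2b <- matrix(rinvgamma1(K * C, ig_shape + 0.5,
                                 ig_rate + as.vector(dev2) / 2), K, C)
      }

      if (t > burn_in && (t - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- c(alpha, if (K > 0) as.vector(beta), mu_alpha,
                         if (K > 0) mu_beta, s2p, s2a,
                         if (K > 0) as.vector(s2b))
      }
    }
    draws[[ch]] <- out
  }

  structure(list(draws = draws, par_names = par_names,
                 intercept_labels = jlab, group_labels = clab,
                 slope_names = slope_names,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thin = thin, chains = chains, seed = seed),
                 fixed = fixed),
            class = "posterior_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine posterior chains into one draw matrix
#'
#' @param x A `posterior_samples` object.
#' @param ... Unused.
#' @return Matrix of stacked retained draws (rows) by parameter (columns).
#' @export
as.matrix.posterior_samples <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' @export
print.posterior_samples <- function(x, ...) {
  s <- x$settings
  cat("Posterior samples:", length(x$par_names), "parameters,",
      s$chains, "chains x", nrow(x$draws[[1]]), "retained draws\n")
  cat("  (", s$iterations, "iterations, burn-in", s$burn_in,
      ", thin", s$thin, ", seed", s$seed, ")\n")
  if (isTRUE(attr(x, "converged") == FALSE))
    cat("  WARNING: convergence not reached (max rhat ",
        format(attr(x, "max_rhat"), digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic between/within-chain variance ratio
#' \eqn{\hat R = \sqrt{\hat V / W}} with
#' \eqn{\hat V = (n-1)/n \, W + B/n} for each parameter, where `W` is the
#' mean within-chain variance and `B/n` the variance of chain means. Values
#' near 1 indicate the chains mix over the same distribution.
#'
#' @param samples A `posterior_samples` object, or a list of draw matrices
#'   (one per chain, equal dimensions).
#' @return Named numeric vector of rhat values.
#' @export
gelman_rubin <- function(samples) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws
           else samples
  m <- length(draws)
  if (m < 2L) stop("Gelman-Rubin diagnostic requires at least 2 chains")
  n <- nrow(draws[[1L]])
  if (n < 10L) stop("need at least 10 retained draws per chain")
  P <- ncol(draws[[1L]])
  means <- matrix(vapply(draws, colMeans, numeric(P)), nrow = P)
  vars <- matrix(vapply(draws, function(d) apply(d, 2, stats::var),
                        numeric(P)), nrow = P)
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)
  V <- (n - 1) / n * W + B_over_n
  rhat <- sqrt(V / W)
  rhat[W == 0 & B_over_n == 0] <- 1
  names(rhat) <- colnames(draws[[1L]])
  rhat
}

#' Summarize posterior draws
#'
#' @param samples A `posterior_samples` object.
#' @param probs Quantiles to report.
#' @return Data frame with one row per parameter: mean, sd, quantiles and
#'   rhat (when at least two chains are present).
#' @export
posterior_summary <- function(samples, probs = c(0.025, 0.5, 0.975)) {
  m <- as.matrix(samples)
  qs <- t(apply(m, 2, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  out <- data.frame(parameter = colnames(m), mean = colMeans(m),
                    sd = apply(m, 2, stats::sd), qs, check.names = FALSE)
  if (length(samples$draws) >= 2L) out$rhat <- gelman_rubin(samples)
  rownames(out) <- NULL
  out
}
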