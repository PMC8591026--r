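#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study design the models assume: nine sites (five
#' open savannas, four closed forests) along a moisture gradient, 54 Past
#' and 49 Modern trees with 72 on savanna sites and 31 on forest sites,
#' monthly climate from 1850 to 2015, and a process standard deviation of
#' 0.3 on log growth.
#'
#' @param seed Integer seed fixing the full generation stream.
#' @param n_sites,n_savanna_sites Site counts.
#' @param precip_mean,june_tmax_mean Per-site water-year precipitation means
#'   (mm) and June maximum temperature means (deg C); defaults span the
#'   study gradient (577--873 mm, 24.1--26.8 deg C).
#' @param precip_shape Gamma shape of monthly precipitation.
#' @param tmax_sd Monthly temperature noise sd (deg C).
#' @param pdsi_phi,pdsi_sd,pdsi_coupling Monthly AR(1) coefficient,
#'   innovation sd and precipitation-anomaly coupling of the drought index.
#' @param years Inclusive simulated calendar span.
#' @param n_past,n_modern Tree counts by cohort.
#' @param n_savanna_trees Trees allocated to savanna sites.
#' @param dbh_scale_mean,dbh_scale_sd Fixed DBH scaling used for the DBH
#'   z-score during generation (recorded in the truth object).
#' @param missing_rate Fraction of rings set missing (not zero); off by
#'   default.
#' @param iso_sites Site indices sampled for isotopes (must include both
#'   structures).
#' @param iso_trees_per_cohort,iso_years_per_cohort Isotope sampling depth.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_sites = 9L, n_savanna_sites = 5L,
                       precip_mean = seq(600, 850, length.out = n_sites),
                       june_tmax_mean = seq(26.8, 24.1, length.out = n_sites),
                       precip_shape = 4, tmax_sd = 1.5,
                       pdsi_phi = 0.9, pdsi_sd = 0.5, pdsi_coupling = 0.5,
                       years = c(1850L, 2015L),
                       n_past = 54L, n_modern = 49L, n_savanna_trees = 72L,
                       dbh_scale_mean = 25, dbh_scale_sd = 10,
                       missing_rate = 0,
                       iso_sites = c(1L, 2L, 3L, 6L, 7L),
                       iso_trees_per_cohort = 4L,
                       iso_years_per_cohort = 10L) {
  site_id <- sprintf("site%d", seq_len(n_sites))
  structure_ <- rep(c("savanna", "forest"),
                    c(n_savanna_sites, n_sites - n_savanna_sites))
  structure(list(seed = as.integer(seed), site_id = site_id,
                 site_structure = structure_, precip_mean = precip_mean,
                 june_tmax_mean = june_tmax_mean,
                 precip_shape = precip_shape, tmax_sd = tmax_sd,
                 pdsi_phi = pdsi_phi, pdsi_sd = pdsi_sd,
                 pdsi_coupling = pdsi_coupling, years = years,
                 n_past = n_past, n_modern = n_modern,
                 n_savanna_trees = n_savanna_trees,
                 dbh_scale_mean = dbh_scale_mean,
                 dbh_scale_sd = dbh_scale_sd,
                 missing_rate = missing_rate, iso_sites = iso_sites,
                 iso_trees_per_cohort = iso_trees_per_cohort,
                 iso_years_per_cohort = iso_years_per_cohort),
            class = "sim_config")
}

#' Generating parameters for the growth model
#'
#' Group slopes default to posterior means reported for the four
#' cohort-by-structure groups in the study this design emulates
#' (precipitation, temperature, interaction, lag-1, lag-2, DBH); process sd
#' defaults to 0.3 on log growth.
#'
#' @param beta 6 x 4 slope matrix (covariates x groups).
#' @param mu_alpha,sigma_alpha Mean and sd of site intercepts (log mm).
#' @param sigma_p Process sd of log growth.
#' @return A list of generating values.
#' @export
default_growth_params <- function(beta = NULL, mu_alpha = 0.05,
                                  sigma_alpha = 0.05, sigma_p = 0.3) {
  groups <- c("Past-Savanna", "Past-Forest", "Modern-Savanna",
              "Modern-Forest")
  if (is.null(beta)) {
    beta <- rbind(
      precip      = c(0.111, 0.129, 0.014, 0.029),
      tmax        = c(-0.073, -0.094, -0.054, -0.081),
      interaction = c(0.010, 0.020, 0.064, 0.030),
      lag1        = c(0.578, 0.513, 0.489, 0.550),
      lag2        = c(0.216, 0.129, 0.387, 0.232),
      dbh         = c(0.010, 0.010, 0.010, 0.010))
    colnames(beta) <- groups
  }
  list(beta = beta, mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
       sigma_p = sigma_p)
}

#' Generating parameters for the isotope (iWUE) model
#'
#' Baselines place past savannas above past forests, with modern baselines
#' inflated by the reported percent increases (12.8% in savannas, 21% in
#' closed forests); slopes default to the reported group estimates where
#' printed and to small plausible values elsewhere.
#'
#' @param alpha Named per-group baselines (micromol/mol).
#' @param beta 3 x 4 slope matrix (precip, tmax, dbh by group), iWUE units
#'   per covariate sd.
#' @param sigma_p Process sd of iWUE.
#' @param savanna_increase_pct,forest_increase_pct Built-in modern/past
#'   baseline percent increases.
#' @return A list of generating values.
#' @export
default_isotope_params <- function(alpha = NULL, beta = NULL, sigma_p = 8,
                                   savanna_increase_pct = 12.8,
                                   forest_increase_pct = 21) {
  groups <- c("Past-Savanna", "Past-Forest", "Modern-Savanna",
              "Modern-Forest")
  if (is.null(alpha)) {
    alpha <- c(95, 85, 95 * (1 + savanna_increase_pct / 100),
               85 * (1 + forest_increase_pct / 100))
    names(alpha) <- groups
  }
  if (is.null(beta)) {
    beta <- rbind(precip = c(-0.706, 0.592, 1.044, 2.52),
                  tmax = c(-0.8, -0.6, -2.47, -1.2),
                  dbh = c(0.5, 0.5, 2.976, 0.5))
    colnames(beta) <- groups
  }
  list(alpha = alpha, beta = beta, sigma_p = sigma_p,
       savanna_increase_pct = savanna_increase_pct,
       forest_increase_pct = forest_increase_pct)
}

#' Synthetic atmospheric CO2 and delta-13-C record
#'
#' A smooth synthetic stand-in for the composite ice-core/observatory
#' record: CO2 rises exponentially from about 285 ppm in 1850 to about
#' 400 ppm in 2015, and atmospheric delta-13-C declines linearly in CO2
#' from -6.4 to about -8.4 permil over the same span. Values are synthetic
#' and documented as such; supply a measured record via
#' [read_atmosphere_csv()] for real analyses.
#'
#' @param years Years covered.
#' @return Data frame `year`, `co2_ppm`, `d13c_atm_permil`.
#' @export
synthetic_atmosphere <- function(years = 1850:2015) {
  ca <- 280 + 5 * exp(log(24) / 165 * (years - 1850))
  d13c <- -6.4 - (ca - 285) * (2.0 / 115)
  data.frame(year = years, co2_ppm = ca, d13c_atm_permil = d13c)
}

#' Simulate monthly climate for every site
#'
#' Monthly precipitation is gamma-distributed around a summer-peaked
#' seasonal profile scaled to each site's annual mean; maximum temperature
#' follows a July-peaked sinusoid pinned to the site's June mean plus
#' normal noise; the drought index is a monthly AR(1) process whose
#' innovations are coupled to the precipitation anomaly, so dry spells are
#' persistent. Fully reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @return Monthly climate table (`site_id`, `year`, `month`, `precip_mm`,
#'   `tmax_C`, `pdsi`).
#' @export
simulate_climate <- function(config = sim_config()) {
  set.seed(config$seed)
  months <- 1:12
  # summer-peaked fraction of annual precipitation per month
  w <- c(0.4, 0.4, 0.8, 1.2, 1.6, 1.8, 1.8, 1.6, 1.2, 0.8, 0.6, 0.4)
  w <- w / sum(w)
  yrs <- config$years[1]:config$years[2]
  out <- vector("list", length(config$site_id))
  for (s in seq_along(config$site_id)) {
    n <- length(yrs) * 12L
    mo <- rep(months, times = length(yrs))
    yr <- rep(yrs, each = 12L)
    mean_p <- config$precip_mean[s] * w[mo]
    shape <- config$precip_shape
    precip <- if (shape > 0)
      stats::rgamma(n, shape = shape, scale = mean_p / shape) else mean_p
    peak <- config$june_tmax_mean[s] + 15 * (1 - cospi((6 - 7) / 6))
    tmax <- peak - 15 * (1 - cospi((mo - 7) / 6)) +
      stats::rnorm(n, 0, config$tmax_sd)
    z_p <- if (shape > 0) (precip - mean_p) / (mean_p / sqrt(shape))
           else rep(0, n)
    pdsi <- numeric(n)
    innov <- config$pdsi_coupling * z_p + stats::rnorm(n, 0, config$pdsi_sd)
    prev <- 0
    for (i in seq_len(n)) {
      prev <- config$pdsi_phi * prev + innov[i]
      pdsi[i] <- prev
    }
    out[[s]] <- data.frame(site_id = config$site_id[s], year = yr,
                           month = mo, precip_mm = precip, tmax_C = tmax,
                           pdsi = pdsi)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Lay out the synthetic tree design
#'
#' Allocates trees to sites (savanna sites carry the larger share),
#' alternates cohorts within the site sequence and adjusts the tail so the
#' configured Past/Modern totals are met exactly, then draws establishment
#' years uniformly within each cohort's window.
#'
#' @param config A [sim_config()].
#' @param seed Seed for establishment years and initial diameters.
#' @return Data frame `tree_id`, `site_id`, `structure`, `cohort`,
#'   `estab_year`, `init_dbh_cm`.
#' @export
simulate_trees <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  n_total <- config$n_past + config$n_modern
  sav <- which(config$site_structure == "savanna")
  forest <- which(config$site_structure == "forest")
  n_forest_trees <- n_total - config$n_savanna_trees
  quota <- integer(length(config$site_id))
  quota[sav] <- diff(round(seq(0, config$n_savanna_trees,
                               length.out = length(sav) + 1L)))
  quota[forest] <- diff(round(seq(0, n_forest_trees,
                                  length.out = length(forest) + 1L)))
  site_idx <- rep(seq_along(config$site_id), times = quota)
  cohort <- rep(c("Past", "Modern"), length.out = n_total)
  excess <- sum(cohort == "Past") - config$n_past
  if (excess > 0)
    cohort[rev(which(cohort == "Past"))[seq_len(excess)]] <- "Modern"
  if (excess < 0)
    cohort[rev(which(cohort == "Modern"))[seq_len(-excess)]] <- "Past"
  # water-year covariates exist only from the second simulated year, and two
  # burn-in years precede each series, so establishment starts at year + 5
  est_min <- config$years[1] + 5L
  estab <- ifelse(cohort == "Past",
                  sample(est_min:1894, n_total, replace = TRUE),
                  sample(1895:1950, n_total, replace = TRUE))
  data.frame(tree_id = sprintf("t%03d", seq_len(n_total)),
             site_id = config$site_id[site_idx],
             structure = config$site_structure[site_idx],
             cohort = cohort, estab_year = as.integer(estab),
             init_dbh_cm = stats::runif(n_total, 0.5, 2))
}

# group label for a cohort/structure pair
cs_group <- function(cohort, structure_) {
  st <- paste0(toupper(substr(structure_, 1, 1)),
               substr(structure_, 2, nchar(structure_)))
  paste(cohort, st, sep = "-")
}

# empirical scaling over the tree-years the assembled table will contain,
# matching scale_covariates(); dbh scaling is fixed by config
generator_scaling <- function(design, annual, config,
                              windows = list(Past = c(1895, 1949),
                                             Modern = c(1950, 2015))) {
  rows <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    win <- windows[[tr$cohort]]
    ys <- max(tr$estab_year + 2L, win[1]):win[2]
    a <- annual[annual$site_id == tr$site_id & annual$year %in% ys, ]
    rows[[i]] <- data.frame(group = cs_group(tr$cohort, tr$structure),
                            wy_precip = a$wy_precip, june_tmax = a$june_tmax)
  }
  d <- do.call(rbind, rows)
  sc <- do.call(rbind, lapply(unique(d$group), function(g) {
    x <- d[d$group == g, ]
    rbind(data.frame(group = g, variable = "wy_precip",
                     mean = mean(x$wy_precip), sd = stats::sd(x$wy_precip)),
          data.frame(group = g, variable = "june_tmax",
                     mean = mean(x$june_tmax), sd = stats::sd(x$june_tmax)),
          data.frame(group = g, variable = "dbh",
                     mean = config$dbh_scale_mean,
                     sd = config$dbh_scale_sd))
  }))
  rownames(sc) <- NULL
  sc
}

#' Simulate ring-width series from the growth model
#'
#' Generates each tree's annual log growth recursively from the linear
#' predictor plus process noise: lag terms are initialized at the
#' deterministic fixed point of the lag recursion given the first year's
#' covariates, the first two generated years are discarded as burn-in (so
#' the returned series starts at the establishment year), and diameter is
#' accumulated forward as twice the radial increment. The covariate
#' z-scores use the exact scaling recorded in the returned truth object, so
#' the pipeline can reproduce them.
#'
#' @param params Generating values (see [default_growth_params()]).
#' @param annual Annual climate table covering every tree-year (from
#'   [annual_climate()] of the simulated monthly record).
#' @param design Tree design from [simulate_trees()].
#' @param config A [sim_config()].
#' @param seed Seed for the growth noise and site intercepts.
#' @return List with `rw` (ring widths, mm), `meta` (census at the final
#'   simulated year) and `truth` (all generating values, site intercepts,
#'   scaling table, seed).
#' @export
simulate_growth <- function(params = default_growth_params(), annual,
                            design, config = sim_config(),
                            seed = config$seed) {
  beta <- params$beta
  lagsum <- abs(beta["lag1", ]) + abs(beta["lag2", ])
  if (any(lagsum >= 1))
    stop("explosive lag configuration: |beta_lag1| + |beta_lag2| >= 1 for ",
         paste(colnames(beta)[lagsum >= 1], collapse = ", "))
  set.seed(seed)
  alpha_s <- stats::rnorm(length(config$site_id), params$mu_alpha,
                          params$sigma_alpha)
  names(alpha_s) <- config$site_id
  scaling <- generator_scaling(design, annual, config)
  sc <- function(g, v) scaling[scaling$group == g & scaling$variable == v, ]

  last_year <- config$years[2]
  rw <- vector("list", nrow(design))
  census_dbh <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    grp <- cs_group(tr$cohort, tr$structure)
    b <- beta[, grp]
    yrs <- (tr$estab_year - 2L):last_year
    a <- annual[annual$site_id == tr$site_id, ]
    ai <- match(yrs, a$year)
    if (anyNA(ai)) stop("annual climate does not cover tree ", tr$tree_id)
    p <- sc(grp, "wy_precip"); t_ <- sc(grp, "june_tmax")
    d_ <- sc(grp, "dbh")
    zp <- (a$wy_precip[ai] - p$mean) / p$sd
    zt <- (a$june_tmax[ai] - t_$mean) / t_$sd
    fixed_part <- alpha_s[tr$site_id] + b["precip"] * zp + b["tmax"] * zt +
      b["interaction"] * zp * zt
    n <- length(yrs)
    eps <- stats::rnorm(n, 0, params$sigma_p)
    zd1 <- (tr$init_dbh_cm - d_$mean) / d_$sd
    l1 <- l2 <- (fixed_part[1] + b["dbh"] * zd1) /
      (1 - b["lag1"] - b["lag2"])
    dbh_prev <- tr$init_dbh_cm
    lg <- numeric(n)
    for (j in seq_len(n)) {
      zd <- (dbh_prev - d_$mean) / d_$sd
      g <- fixed_part[j] + b["lag1"] * l1 + b["lag2"] * l2 + b["dbh"] * zd
      lg[j] <- g + eps[j]
      w <- exp(lg[j])
      dbh_prev <- dbh_prev + 2 * w / 10
      l2 <- l1
      l1 <- lg[j]
    }
    if (any(!is.finite(lg)))
      stop("simulated growth diverged for tree ", tr$tree_id,
           "; the lag/DBH configuration amplifies growth without bound")
    keep <- 3:n   # discard the two burn-in years
    width <- exp(lg[keep])
    if (config$missing_rate > 0) {
      miss <- stats::runif(length(width)) < config$missing_rate
      width[miss] <- NA_real_
    }
    rw[[i]] <- data.frame(tree_id = tr$tree_id, site_id = tr$site_id,
                          year = yrs[keep], width_mm = width)
    census_dbh[i] <- dbh_prev
  }
  meta <- data.frame(tree_id = design$tree_id, site_id = design$site_id,
                     census_dbh_cm = census_dbh, census_year = last_year,
                     structure = design$structure)
  list(rw = do.call(rbind, c(rw, list(make.row.names = FALSE))),
       meta = meta,
       truth = list(beta = beta, alpha_s = alpha_s,
                    mu_alpha = params$mu_alpha,
                    sigma_alpha = params$sigma_alpha,
                    sigma_p = params$sigma_p, scaling = scaling,
                    design = design, seed = seed))
}

#' Simulate latewood isotope measurements consistent with the iWUE model
#'
#' For each isotope site, selects climate-matched year pairs across the two
#' cohort windows ([select_matched_years()]), draws iWUE for each sampled
#' tree-year from the hierarchical isotope model, and inverts the
#' discrimination equations through that year's ambient CO2 and atmospheric
#' delta-13-C to produce raw plant delta-13-C values that require Suess
#' correction downstream.
#'
#' @param params Generating values (see [default_isotope_params()]).
#' @param annual Annual climate table.
#' @param monthly Monthly climate table (for matched-year selection).
#' @param atm Atmosphere record covering the sampled years.
#' @param config A [sim_config()].
#' @param seed Seed.
#' @param max_retry Resampling cap for draws implying discrimination
#'   outside (0, b).
#' @return List with `iso` (one row per tree-year with raw delta-13-C and
#'   covariates) and `truth` (generating values, scaling, matched years).
#' @export
simulate_isotopes <- function(params = default_isotope_params(), annual,
                              monthly, atm, config = sim_config(),
                              seed = config$seed, max_retry = 100L) {
  set.seed(seed)
  consts <- fractionation_constants()
  windows <- list(Past = c(1895, 1949), Modern = c(1950, 2015))
  rows <- list(); matched <- list()
  for (s in config$iso_sites) {
    sid <- config$site_id[s]
    st <- config$site_structure[s]
    pairs <- select_matched_years(monthly[monthly$site_id == sid, ],
                                  windows$Past, windows$Modern,
                                  k = config$iso_years_per_cohort)
    matched[[sid]] <- pairs
    for (coh in c("Past", "Modern")) {
      yrs <- if (coh == "Past") pairs$past_year else pairs$modern_year
      for (tr in seq_len(config$iso_trees_per_cohort)) {
        tid <- sprintf("%s-%s%d", sid, substr(coh, 1, 1), tr)
        dbh <- stats::runif(1, 20, 40)
        a <- annual[annual$site_id == sid & annual$year %in% yrs, ]
        rows[[length(rows) + 1L]] <- data.frame(
          tree_id = tid, site_id = sid, year = a$year, cohort = coh,
          structure = st, group = cs_group(coh, st), dbh = dbh,
          wy_precip = a$wy_precip, june_tmax = a$june_tmax)
      }
    }
  }
  iso <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  scaling <- do.call(rbind, lapply(unique(iso$group), function(g) {
    x <- iso[iso$group == g, ]
    rbind(data.frame(group = g, variable = "wy_precip",
                     mean = mean(x$wy_precip), sd = stats::sd(x$wy_precip)),
          data.frame(group = g, variable = "june_tmax",
                     mean = mean(x$june_tmax), sd = stats::sd(x$june_tmax)),
          data.frame(group = g, variable = "dbh", mean = mean(x$dbh),
                     sd = stats::sd(x$dbh)))
  }))
  sc <- function(g, v) scaling[scaling$group == g & scaling$variable == v, ]
  zp <- zt <- zd <- numeric(nrow(iso))
  for (g in unique(iso$group)) {
    i <- iso$group == g
    p <- sc(g, "wy_precip"); t_ <- sc(g, "june_tmax"); d_ <- sc(g, "dbh")
    zp[i] <- (iso$wy_precip[i] - p$mean) / p$sd
    zt[i] <- (iso$june_tmax[i] - t_$mean) / t_$sd
    zd[i] <- (iso$dbh[i] - d_$mean) / d_$sd
  }
  mu <- params$alpha[iso$group] + params$beta["precip", iso$group] * zp +
    params$beta["tmax", iso$group] * zt + params$beta["dbh", iso$group] * zd

  ai <- match(iso$year, atm$year)
  if (anyNA(ai)) stop("atmosphere record does not cover all sampled years")
  ca <- atm$co2_ppm[ai]; d_atm <- atm$d13c_atm_permil[ai]
  iwue_true <- stats::rnorm(nrow(iso), mu, params$sigma_p)
  delta <- consts$b -
    consts$k_diff * (consts$b - consts$a) * iwue_true / ca
  bad <- which(delta <= 0 | delta >= consts$b)
  tries <- 0L
  while (length(bad) && tries < max_retry) {
    iwue_true[bad] <- stats::rnorm(length(bad), mu[bad], params$sigma_p)
    delta[bad] <- consts$b -
      consts$k_diff * (consts$b - consts$a) * iwue_true[bad] / ca[bad]
    bad <- bad[delta[bad] <= 0 | delta[bad] >= consts$b]
    tries <- tries + 1L
  }
  if (length(bad))
    stop("could not generate physiological discrimination after ",
         max_retry, " retries")
  iso$d13c_raw_permil <- (d_atm - delta) / (1 + delta / 1000)
  iso$iwue_true <- iwue_true
  iso$group <- factor(iso$group, levels = c("Past-Savanna", "Past-Forest",
                                            "Modern-Savanna",
                                            "Modern-Forest"))
  iso$group <- droplevels(iso$group)
  list(iso = iso,
       truth = list(alpha = params$alpha, beta = params$beta,
                    sigma_p = params$sigma_p, scaling = scaling,
                    matched_years = matched, seed = seed))
}

#' Simulate the full synthetic study
#'
#' Runs climate, tree-design, growth and isotope generation off one seed
#' and returns everything a pipeline run needs, including the atmosphere
#' record and the truth objects for recovery checks.
#'
#' @param seed Integer seed; stage seeds are derived from it.
#' @param config A [sim_config()]; its seed is overridden by `seed`.
#' @param growth_params,iso_params Generating values.
#' @return List: `config`, `monthly`, `annual`, `atmosphere`, `design`,
#'   `rw`, `meta`, `iso`, `truth` (`$growth`, `$isotope`).
#' @export
simulate_study <- function(seed = 1L, config = sim_config(seed = seed),
                           growth_params = default_growth_params(),
                           iso_params = default_isotope_params()) {
  config$seed <- as.integer(seed)
  monthly <- simulate_climate(config)
  annual <- annual_climate(monthly, quiet = TRUE)
  atm <- synthetic_atmosphere(config$years[1]:config$years[2])
  design <- simulate_trees(config, seed = config$seed + 1L)
  gr <- simulate_growth(growth_params, annual, design, config,
                        seed = config$seed + 2L)
  iso <- simulate_isotopes(iso_params, annual, monthly, atm, config,
                           seed = config$seed + 3L)
  list(config = config, monthly = monthly, annual = annual,
       atmosphere = atm, design = design, rw = gr$rw, meta = gr$meta,
       iso = iso$iso, truth = list(growth = gr$truth, isotope = iso$truth))
}
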