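#' Build a covariate grid for posterior prediction
#'
#' Grid points are combinations of June maximum temperature and water-year
#' precipitation in natural units; all other covariates are held at group
#' reference values computed from the observation table: both lag terms at
#' the within-group mean log growth and DBH at the within-group mean
#' diameter. Historical covariate ranges are stored per group so that
#' out-of-range grid points can be flagged as extrapolation.
#'
#' @param obs Scaled, grouped observation table used for the fit.
#' @param tmax,precip Numeric vectors of grid values (deg C, mm).
#' @param groups Group labels to predict for (default: all in `obs`).
#' @return A `covariate_grid` list with `grid` (one row per group x tmax x
#'   precip), `reference` (per-group lag and dbh values) and `ranges`.
#' @export
covariate_grid <- function(obs, tmax, precip, groups = levels(obs$group)) {
  reference <- do.call(rbind, lapply(groups, function(g) {
    i <- obs$group == g
    data.frame(group = g, lag = mean(obs$log_growth[i]),
               dbh = mean(obs$dbh[i]))
  }))
  ranges <- do.call(rbind, lapply(groups, function(g) {
    i <- obs$group == g
    data.frame(group = g,
               tmax_min = min(obs$june_tmax[i]),
               tmax_max = max(obs$june_tmax[i]),
               precip_min = min(obs$wy_precip[i]),
               precip_max = max(obs$wy_precip[i]))
  }))
  grid <- expand.grid(group = groups, june_tmax = tmax, wy_precip = precip,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(grid = grid, reference = reference, ranges = ranges),
            class = "covariate_grid")
}

#' Posterior-predictive growth over a covariate grid
#'
#' For every retained posterior draw and grid point, evaluates the linear
#' predictor (site intercept taken as the per-draw mean over sites, i.e. a
#' typical site) and transforms to ring width: `exp(g + eps)` with process
#' error `eps ~ N(0, sigma2_p)` when `include_process_error`, else
#' `exp(g)`. Summaries are the median and the 2.5/97.5 percentiles over
#' draws. Grid points outside a group's historical covariate range carry an
#' `extrapolated` flag.
#'
#' @param fit A fitted growth model.
#' @param grid A [covariate_grid()].
#' @param scaling Scaling table used for the fit (from [scale_covariates()]).
#' @param include_process_error Add process error to the predictive draws.
#' @param seed Seed for the process-error draws.
#' @return A `growth_prediction` object: `$table` with per-point medians and
#'   95% intervals (mm/yr), `$mu_draws` (draws x points, process-error-free)
#'   and `$pred_draws` matrices, and the grid metadata.
#' @export
posterior_predict <- function(fit, grid, scaling, include_process_error = TRUE,
                              seed = 1L) {
  stopifnot(inherits(grid, "covariate_grid"))
  g <- grid$grid
  if (!all(g$group %in% fit$group_labels))
    stop("grid groups missing from fit: ",
         paste(setdiff(unique(g$group), fit$group_labels), collapse = ", "))
  if (!all(g$group %in% scaling$group))
    stop("scaling params missing for grid group(s)")
  spec <- fit$spec
  sc_get <- function(var, grp, x) {
    p <- scaling[scaling$variable == var, ]
    (x - p$mean[match(grp, p$group)]) / p$sd[match(grp, p$group)]
  }
  ref <- grid$reference
  pz <- sc_get("wy_precip", g$group, g$wy_precip)
  tz <- sc_get("june_tmax", g$group, g$june_tmax)
  dz <- sc_get("dbh", g$group, ref$dbh[match(g$group, ref$group)])
  lag <- ref$lag[match(g$group, ref$group)]
  Xg <- cbind(precip = pz, tmax = tz, interaction = pz * tz,
              lag1 = lag, lag2 = lag, dbh = dz)[, spec$covariates,
                                                drop = FALSE]

  M <- as.matrix(fit)
  n_draw <- nrow(M)
  n_pt <- nrow(g)
  a_cols <- paste0("alpha[", fit$intercept_labels, "]")
  alpha_bar <- rowMeans(M[, a_cols, drop = FALSE])
  mu_draws <- matrix(NA_real_, n_draw, n_pt)
  for (grp in unique(g$group)) {
    pts <- which(g$group == grp)
    b_cols <- paste0("beta[", spec$covariates, ",", grp, "]")
    B <- M[, b_cols, drop = FALSE]                 # draws x K
    mu_draws[, pts] <- alpha_bar + B %*% t(Xg[pts, , drop = FALSE])
  }
  set.seed(as.integer(seed))
  pred_draws <- exp(mu_draws)
  if (include_process_error) {
    eps <- matrix(stats::rnorm(n_draw * n_pt, 0,
                               sqrt(M[, "sigma2_p"])), n_draw, n_pt)
    pred_draws <- exp(mu_draws + eps)
  }
  mu_draws <- exp(mu_draws)

  rng <- grid$ranges[match(g$group, grid$ranges$group), ]
  g$extrapolated <- g$june_tmax < rng$tmax_min | g$june_tmax > rng$tmax_max |
    g$wy_precip < rng$precip_min | g$wy_precip > rng$precip_max
  qs <- apply(pred_draws, 2, stats::quantile, c(0.025, 0.5, 0.975))
  g$growth_median <- qs[2, ]
  g$growth_lo <- qs[1, ]
  g$growth_hi <- qs[3, ]
  structure(list(table = g, mu_draws = mu_draws, pred_draws = pred_draws,
                 include_process_error = include_process_error,
                 reference = grid$reference),
            class = "growth_prediction")
}

#' Percent change in predicted growth versus a reference temperature
#'
#' For each group and precipitation level, computes per draw
#' `100 * (growth(t) - growth(ref)) / growth(ref)` against the grid point
#' at the reference temperature, using the process-error-free draws (the
#' shared process error cancels in the ratio). Summaries are the median
#' and 95% equal-tailed interval.
#'
#' @param pred A `growth_prediction`.
#' @param ref_tmax Reference June maximum temperature, which must be one of
#'   the grid's temperature values (default 26, the regional median).
#' @return The prediction table with `pct_change_median`, `pct_change_lo`,
#'   `pct_change_hi` columns added; per-draw contrasts in
#'   `attr(, "contrast_draws")`.
#' @export
percent_change_vs_reference <- function(pred, ref_tmax = 26) {
  g <- pred$table
  out <- g
  cd <- matrix(NA_real_, nrow(pred$mu_draws), nrow(g))
  for (grp in unique(g$group)) {
    for (p in unique(g$wy_precip[g$group == grp])) {
      pts <- which(g$group == grp & g$wy_precip == p)
      ref_pt <- pts[g$june_tmax[pts] == ref_tmax]
      if (length(ref_pt) != 1L)
        stop("reference temperature ", ref_tmax,
             " not present in grid for group ", grp)
      ref_draws <- pred$mu_draws[, ref_pt]
      cd[, pts] <- 100 * (pred$mu_draws[, pts] - ref_draws) / ref_draws
    }
  }
  qs <- apply(cd, 2, stats::quantile, c(0.025, 0.5, 0.975))
  out$pct_change_median <- qs[2, ]
  out$pct_change_lo <- qs[1, ]
  out$pct_change_hi <- qs[3, ]
  attr(out, "contrast_draws") <- cd
  attr(out, "ref_tmax") <- ref_tmax
  out
}

#' Cohort growth benefit across a shared covariate grid
#'
#' Percent difference in predicted growth, modern versus past group, at
#' every grid point. When both predictions come from the same fit the
#' contrast is paired by draw index; otherwise draws are aligned by index
#' as an independent pairing and flagged accordingly.
#'
#' @param pred_modern,pred_past `growth_prediction` objects over identical
#'   (tmax, precip) grids, one group each or sharing group structure.
#' @param modern,past Group labels selecting the rows to contrast.
#' @return Data frame with per-point posterior mean percent difference and
#'   95% interval; `attr(, "paired")` records the pairing.
#' @export
cohort_benefit <- function(pred_modern, pred_past, modern, past) {
  gm <- pred_modern$table; gp <- pred_past$table
  im <- which(gm$group == modern)
  ip <- which(gp$group == past)
  if (length(im) == 0L || length(ip) == 0L)
    stop("requested groups not present in predictions")
  if (length(im) != length(ip) ||
      any(gm$june_tmax[im] != gp$june_tmax[ip]) ||
      any(gm$wy_precip[im] != gp$wy_precip[ip]))
    stop("grids are not aligned between the two predictions")
  dm <- pred_modern$mu_draws[, im, drop = FALSE]
  dp <- pred_past$mu_draws[, ip, drop = FALSE]
  if (nrow(dm) != nrow(dp))
    stop("draw counts differ; refit or thin to align")
  pct <- 100 * (dm - dp) / dp
  qs <- apply(pct, 2, stats::quantile, c(0.025, 0.5, 0.975))
  out <- data.frame(june_tmax = gm$june_tmax[im],
                    wy_precip = gm$wy_precip[im],
                    benefit_mean = colMeans(pct),
                    benefit_median = qs[2, ],
                    benefit_lo = qs[1, ], benefit_hi = qs[3, ])
  attr(out, "paired") <- TRUE
  out
}

#' Summarize climate-scenario projections by period and pathway
#'
#' Aggregates a long-format scenario table (columns `model`, `rcp`, `year`,
#' `june_tmax`, `annual_precip`) over inclusive year periods; a year falling
#' in two listed periods (e.g. 2075) is assigned to the later one, and the
#' convention is recorded on the output. Values outside a supplied
#' historical range are flagged.
#'
#' @param scen Scenario data frame.
#' @param periods List of inclusive `c(first, last)` year ranges.
#' @param hist_tmax_range,hist_precip_range Optional historical ranges used
#'   to flag extrapolation.
#' @return Data frame: per period and rcp, the mean/min/max of `june_tmax`
#'   and `annual_precip` across models and years, with extrapolation flags.
#' @export
summarize_scenarios <- function(scen,
                                periods = list(c(2025, 2049), c(2050, 2075),
                                               c(2075, 2099)),
                                hist_tmax_range = NULL,
                                hist_precip_range = NULL) {
  need <- c("model", "rcp", "year", "june_tmax", "annual_precip")
  if (!all(need %in% names(scen)))
    stop("scenario table must have columns ", paste(need, collapse = ", "))
  # assign each year to the LAST listed period containing it
  scen$period <- NA_character_
  for (p in periods) {
    lab <- paste0(p[1], "-", p[2])
    scen$period[scen$year >= p[1] & scen$year <= p[2]] <- lab
  }
  scen <- scen[!is.na(scen$period), ]
  rows <- list()
  for (lab in unique(scen$period)) {
    for (r in unique(scen$rcp[scen$period == lab])) {
      s <- scen[scen$period == lab & scen$rcp == r, ]
      if (nrow(s) == 0L) { warning("empty period ", lab, "; omitted"); next }
      rows[[paste(lab, r)]] <- data.frame(
        period = lab, rcp = r, n = nrow(s),
        tmax_mean = mean(s$june_tmax), tmax_min = min(s$june_tmax),
        tmax_max = max(s$june_tmax),
        precip_mean = mean(s$annual_precip), precip_min = min(s$annual_precip),
        precip_max = max(s$annual_precip))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(hist_tmax_range))
    out$tmax_outside_hist <- out$tmax_max > max(hist_tmax_range) |
      out$tmax_min < min(hist_tmax_range)
  if (!is.null(hist_precip_range))
    out$precip_outside_hist <- out$precip_max > max(hist_precip_range) |
      out$precip_min < min(hist_precip_range)
  attr(out, "period_convention") <-
    "inclusive endpoints; overlapping years assigned to the later period"
  out
}
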