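#' Read a monthly climate CSV
#'
#' Expected columns: `site_id`, `year`, `month` (1--12), `precip_mm`,
#' `tmax_C`, `pdsi`. One row per site-year-month.
#'
#' @param path CSV path.
#' @param quiet Suppress the row-count message.
#' @return Validated data frame.
#' @export
read_monthly_climate <- function(path, quiet = FALSE) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "month", "precip_mm", "tmax_C", "pdsi")
  if (!all(need %in% names(cl)))
    stop("monthly climate CSV must have columns ",
         paste(need, collapse = ", "))
  validate_monthly_climate(cl)
  if (!quiet) message("read ", nrow(cl), " site-months from ", basename(path))
  cl[need]
}

validate_monthly_climate <- function(cl) {
  if (any(cl$month < 1 | cl$month > 12)) stop("month must be in 1..12")
  if (anyDuplicated(cl[c("site_id", "year", "month")]))
    stop("duplicate (site_id, year, month) rows in monthly climate")
  invisible(cl)
}

#' Annual climate covariates from monthly records
#'
#' For each site and growth year computes: `wy_precip`, the water-year
#' precipitation total (October of the previous calendar year through
#' September, mm); `june_tmax`, June maximum temperature (deg C); and
#' `jja_pdsi`, the June--August mean Palmer Drought Severity Index. A
#' site-year appears only when every contributing month is present; years
#' with incomplete records are omitted.
#'
#' @param monthly Monthly climate table (see [read_monthly_climate()]).
#' @param quiet Suppress the omission message.
#' @return Data frame with `site_id`, `year`, `wy_precip`, `june_tmax`,
#'   `jja_pdsi`.
#' @export
annual_climate <- function(monthly, quiet = FALSE) {
  validate_monthly_climate(monthly)
  out <- list()
  for (sid in unique(monthly$site_id)) {
    m <- monthly[monthly$site_id == sid, ]
    key <- paste(m$year, m$month)
    lookup <- function(yr, mo, col)
      m[[col]][match(paste(yr, mo), key)]
    yrs <- sort(unique(m$year))
    wy <- vapply(yrs, function(y) {
      mm <- c(lookup(rep(y - 1L, 3L), 10:12, "precip_mm"),
              lookup(rep(y, 9L), 1:9, "precip_mm"))
      if (anyNA(mm)) NA_real_ else sum(mm)
    }, numeric(1))
    jt <- lookup(yrs, rep(6L, length(yrs)), "tmax_C")
    pdsi <- vapply(yrs, function(y) {
      p <- lookup(rep(y, 3L), 6:8, "pdsi")
      if (anyNA(p)) NA_real_ else mean(p)
    }, numeric(1))
    keep <- !is.na(wy) & !is.na(jt) & !is.na(pdsi)
    if (any(!keep) && !quiet)
      message("site ", sid, ": omitted ", sum(!keep),
              " years with incomplete monthly climate")
    out[[sid]] <- data.frame(site_id = sid, year = yrs[keep],
                             wy_precip = wy[keep], june_tmax = jt[keep],
                             jja_pdsi = pdsi[keep])
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (any(res$wy_precip < 0)) stop("negative water-year precipitation")
  res
}

#' Restrict observations to drought years
#'
#' The climate record contains long-term wetting trends that can confound
#' estimated drought responses; restricting the analysis to the drier years
#' reduces that influence. Within each (site, cohort) group, observation
#' years whose June--August PDSI lies at or below the group's `q` quantile
#' are retained, i.e. the wettest `1 - q` fraction of years is discarded.
#' Quantiles use the linear-interpolation convention (R type 7). Groups with
#' fewer than `min_years` distinct years are retained unfiltered with a
#' warning.
#'
#' @param obs Observation table with `site_id`, `cohort`, `year`.
#' @param annual Annual climate table carrying `jja_pdsi`.
#' @param q Retained quantile (default 0.75).
#' @param min_years Minimum distinct years for filtering.
#' @return Filtered observation table, with attributes `quantile_type` and
#'   `q` recording the convention.
#' @export
drought_filter <- function(obs, annual, q = 0.75, min_years = 4L) {
  stopifnot(q > 0, q <= 1)
  key <- paste(obs$site_id, obs$year)
  pdsi <- annual$jja_pdsi[match(key, paste(annual$site_id, annual$year))]
  if (anyNA(pdsi))
    stop("jja_pdsi undefined for some observation years")
  keep <- rep(TRUE, nrow(obs))
  for (sid in unique(obs$site_id)) {
    for (coh in unique(obs$cohort)) {
      g <- which(obs$site_id == sid & obs$cohort == coh)
      if (!length(g)) next
      yrs <- unique(obs$year[g])
      if (length(yrs) < min_years) {
        warning("site ", sid, " cohort ", coh, ": only ", length(yrs),
                " distinct years; retained unfiltered")
        next
      }
      pd_years <- pdsi[g][match(yrs, obs$year[g])]
      thr <- stats::quantile(pd_years, q, type = 7, names = FALSE)
      keep[g] <- pdsi[g] <= thr
    }
  }
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q") <- q
  attr(out, "quantile_type") <- 7L
  out
}

#' Scale covariates within cohort / cohort-structure groups
#'
#' Water-year precipitation, June maximum temperature and DBH are z-scored
#' by the mean and standard deviation of their group (cohort, or cohort by
#' stand structure), so slope coefficients are comparable across groups.
#' The temperature-by-precipitation interaction column is the product of the
#' two z-scores. The scaling parameters are returned (and accepted back) so
#' prediction grids can be placed on the same scale.
#'
#' @param obs Observation table carrying a `group` column (see
#'   [make_groups()]) and raw `wy_precip`, `june_tmax`, `dbh`.
#' @param params Optional pre-computed scaling table (as returned in
#'   `$scaling`); when supplied it is applied instead of re-estimated.
#' @return List with `observations` (z-score columns `precip_scaled`,
#'   `tmax_scaled`, `interaction`, `dbh_scaled` added) and `scaling`
#'   (data frame `group`, `variable`, `mean`, `sd`).
#' @export
scale_covariates <- function(obs, params = NULL) {
  if (is.null(obs$group)) stop("obs must carry a 'group' column; see make_groups()")
  vars <- c(precip_scaled = "wy_precip", tmax_scaled = "june_tmax",
            dbh_scaled = "dbh")
  if (is.null(params)) {
    params <- do.call(rbind, lapply(levels(obs$group), function(g) {
      idx <- obs$group == g
      do.call(rbind, lapply(unname(vars), function(v) {
        x <- obs[[v]][idx]
        if (length(unique(x)) < 2L)
          stop("group ", g, ", covariate ", v, ": fewer than 2 distinct values")
        s <- stats::sd(x)
        if (s == 0) stop("group ", g, ", covariate ", v, ": zero sd")
        data.frame(group = g, variable = v, mean = mean(x), sd = s)
      }))
    }))
    rownames(params) <- NULL
  }
  for (i in seq_along(vars)) {
    zcol <- names(vars)[i]; v <- vars[[i]]
    p <- params[params$variable == v, ]
    mu <- p$mean[match(obs$group, p$group)]
    sd_ <- p$sd[match(obs$group, p$group)]
    if (anyNA(mu)) stop("scaling params missing for some groups (", v, ")")
    obs[[zcol]] <- (obs[[v]] - mu) / sd_
  }
  obs$interaction <- obs$precip_scaled * obs$tmax_scaled
  list(observations = obs, scaling = params)
}

#' Invert covariate scaling
#'
#' @param value z-scored values.
#' @param group Group labels, recycled against `value`.
#' @param variable Raw variable name (`"wy_precip"`, `"june_tmax"`, `"dbh"`).
#' @param scaling Scaling table from [scale_covariates()].
#' @return Values on the raw scale.
#' @export
unscale_covariate <- function(value, group, variable, scaling) {
  p <- scaling[scaling$variable == variable, ]
  mu <- p$mean[match(group, p$group)]
  sd_ <- p$sd[match(group, p$group)]
  value * sd_ + mu
}

#' Stratified train/test split
#'
#' Rows are split at random within each (site, cohort) stratum so that the
#' training fraction is preserved per stratum (to nearest-integer rounding),
#' mirroring the hierarchical design. Reproducible under `seed`.
#'
#' @param obs Observation table.
#' @param frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
train_test_split <- function(obs, frac = 0.75, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  set.seed(seed)
  n <- nrow(obs)
  in_train <- rep(FALSE, n)
  strata <- interaction(obs$site_id, obs$cohort, drop = TRUE)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) == 0L) next
    n_train <- round(frac * length(idx))
    if (n_train == 0L) {
      warning("stratum ", s, " too small; placed wholly in train")
      n_train <- length(idx)
    }
    in_train[sample(idx, n_train)] <- TRUE
  }
  train <- obs[in_train, , drop = FALSE]
  test <- obs[!in_train, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  attr(train, "seed") <- seed
  list(train = train, test = test)
}

#' Select climate-matched year pairs for isotope sampling
#'
#' Isotope samples are drawn from years whose climates are as similar as
#' possible across the two cohort periods, so cohort contrasts are not
#' confounded by climate. All candidate years (both windows) with complete
#' monthly climate enter a correlation-matrix PCA over the 36 monthly
#' variables (12 precipitation, 12 maximum temperature, 12 PDSI); pairs of
#' (past-window, modern-window) years are then matched greedily by smallest
#' Euclidean distance in the (PC1, PC2) plane. Ties break toward the earlier
#' past year, then the earlier modern year.
#'
#' @param monthly Monthly climate for one site.
#' @param past_window,modern_window Length-2 year ranges (inclusive).
#' @param k Number of disjoint pairs requested.
#' @return Data frame `past_year`, `modern_year`, `distance`, ordered by
#'   selection; fewer than `k` rows (with a warning) when a window is short.
#' @export
select_matched_years <- function(monthly, past_window, modern_window,
                                 k = 10L) {
  if (length(unique(monthly$site_id)) > 1L)
    stop("select_matched_years expects monthly climate for a single site")
  yr_mat <- function(years) {
    m <- sapply(1:12, function(mo) {
      i <- match(paste(years, mo), paste(monthly$year, monthly$month))
      cbind(monthly$precip_mm[i], monthly$tmax_C[i], monthly$pdsi[i])
    }, simplify = "array")  # years x 3 x 12
    matrix(m, nrow = length(years))
  }
  win_years <- function(w) {
    ys <- w[1]:w[2]
    ys[vapply(ys, function(y)
      sum(monthly$year == y) == 12L && !anyNA(
        monthly[monthly$year == y, c("precip_mm", "tmax_C", "pdsi")]),
      logical(1))]
  }
  py <- win_years(past_window)
  my <- win_years(modern_window)
  if (length(py) < 1L || length(my) < 1L)
    stop("no complete years in one of the windows")
  all_years <- c(py, my)
  X <- yr_mat(all_years)
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  sc <- pc$x[, 1:2, drop = FALSE]
  ip <- seq_along(py)
  im <- length(py) + seq_along(my)
  d <- as.matrix(stats::dist(sc))[ip, im, drop = FALSE]
  k_eff <- min(k, length(py), length(my))
  if (k_eff < k)
    warning("only ", k_eff, " matched pairs feasible (requested ", k, ")")
  pairs <- data.frame(past_year = integer(k_eff), modern_year = integer(k_eff),
                      distance = numeric(k_eff))
  avail_p <- rep(TRUE, length(py)); avail_m <- rep(TRUE, length(my))
  for (j in seq_len(k_eff)) {
    dd <- d
    dd[!avail_p, ] <- Inf
    dd[, !avail_m] <- Inf
    best <- min(dd)
    cand <- which(dd == best, arr.ind = TRUE)
    cand <- cand[order(py[cand[, 1]], my[cand[, 2]]), , drop = FALSE]
    pi <- cand[1, 1]; mi <- cand[1, 2]
    pairs$past_year[j] <- py[pi]
    pairs$modern_year[j] <- my[mi]
    pairs$distance[j] <- best
    avail_p[pi] <- FALSE; avail_m[mi] <- FALSE
  }
  pairs
}
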