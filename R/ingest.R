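#' Assign an establishment cohort
#'
#' Trees are grouped by the CO2 environment they established under: the
#' "Past" cohort established before 1895 (low CO2), the "Modern" cohort
#' between 1895 and 1950 inclusive (higher CO2). Establishment year is taken
#' as the year of the innermost measured ring (no pith-offset correction).
#'
#' @param establishment_year Integer vector of first-ring years.
#' @param past_end First Modern year (default 1895).
#' @param modern_end Last Modern establishment year (default 1950).
#' @return Factor with levels `Past`, `Modern`, `Excluded`.
#' @examples
#' assign_cohort(c(1894, 1895, 1950, 1951))
#' @export
assign_cohort <- function(establishment_year, past_end = 1895,
                          modern_end = 1950) {
  out <- ifelse(establishment_year < past_end, "Past",
         ifelse(establishment_year <= modern_end, "Modern", "Excluded"))
  factor(out, levels = c("Past", "Modern", "Excluded"))
}

#' Read a tree metadata CSV
#'
#' Expected columns: `tree_id`, `site_id`, `census_dbh_cm`, `census_year`,
#' `structure` (one of `savanna`, `forest`).
#'
#' @param path CSV path.
#' @param quiet Suppress the row-count message.
#' @return Validated data frame.
#' @export
read_tree_meta <- function(path, quiet = FALSE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "site_id", "census_dbh_cm", "census_year", "structure")
  if (!all(need %in% names(m)))
    stop("metadata CSV must have columns ", paste(need, collapse = ", "))
  if (any(m$census_dbh_cm <= 0)) stop("census_dbh_cm must be positive")
  if (!all(m$structure %in% c("savanna", "forest")))
    stop("structure must be 'savanna' or 'forest'")
  if (anyDuplicated(m$tree_id)) stop("duplicate tree_id in metadata")
  if (!quiet) message("read metadata for ", nrow(m), " trees")
  m[need]
}

#' Reconstruct annual diameter from ring widths and a census diameter
#'
#' Anchors the diameter series at the censused DBH and steps backwards in
#' time, subtracting twice each year's ring width (diameter growth is twice
#' the radial increment; bark is ignored, a constant offset absorbed by
#' later covariate scaling). Returned diameters are end-of-year values:
#' `dbh_cm[year]` includes the ring laid down in `year`. Reconstruction is
#' floored at 0.1 cm.
#'
#' @param series Data frame with `year` and `width_mm` for one tree,
#'   consecutive years.
#' @param census_dbh_cm Censused diameter at breast height (cm).
#' @param census_year Year of the census; must not precede the series.
#' @return Data frame with `year` and `dbh_cm` over the series years.
#' @examples
#' s <- data.frame(year = 1991:2000, width_mm = 2)
#' reconstruct_dbh(s, census_dbh_cm = 30, census_year = 2000)
#' @export
reconstruct_dbh <- function(series, census_dbh_cm, census_year) {
  yrs <- series$year
  if (nrow(series) > 1L && any(diff(yrs) != 1L))
    stop("series years must be consecutive")
  if (census_year < yrs[1L])
    stop("census_year (", census_year, ") precedes the first ring year (",
         yrs[1L], ")")
  # rings after the series end (unmeasured) contribute no decrement
  incr_cm <- 2 * series$width_mm / 10
  dbh <- numeric(length(yrs))
  last <- min(census_year, yrs[length(yrs)])
  dbh[yrs == last] <- census_dbh_cm
  for (y in rev(yrs[yrs < last]))
    dbh[yrs == y] <- dbh[yrs == y + 1L] - incr_cm[yrs == y + 1L]
  if (any(dbh < 0.1)) {
    warning("reconstructed DBH fell below 0.1 cm; floored")
    dbh <- pmax(dbh, 0.1)
  }
  data.frame(year = yrs, dbh_cm = dbh)
}

#' Assemble the growth modelling table
#'
#' Joins ring widths, tree metadata and annual climate into one observation
#' table for the hierarchical growth model. Rows are restricted to each
#' cohort's analysis window (Past trees in 1895--1949, Modern trees in
#' 1950--2015); the first two measured years of every tree are dropped (no
#' lags available); zero or missing widths are treated as missing, removing
#' the row itself and the two rows that would use it as a lag. The DBH
#' covariate for year `t` is the reconstructed diameter at the end of year
#' `t - 1`, i.e. the size the tree carried into the growth year.
#'
#' @param rw Ring-width data frame (`tree_id`, `site_id`, `year`,
#'   `width_mm`), one series per tree (see [average_cores()]).
#' @param meta Tree metadata (see [read_tree_meta()]).
#' @param annual Annual climate table from [annual_climate()].
#' @param windows Named list of cohort analysis windows.
#' @param quiet Suppress exclusion messages.
#' @return A `growth_observations` data frame: identifiers, `cohort`,
#'   `structure`, `log_growth` (ln mm), `lag1_log_growth`, `lag2_log_growth`,
#'   `wy_precip`, `june_tmax`, `dbh` (cm). Covariate z-scores are added later
#'   by [scale_covariates()].
#' @export
assemble_observations <- function(rw, meta, annual,
                                  windows = list(Past = c(1895, 1949),
                                                 Modern = c(1950, 2015)),
                                  quiet = FALSE) {
  rows <- vector("list", nrow(meta))
  dropped <- character(0)
  for (i in seq_len(nrow(meta))) {
    tm <- meta[i, ]
    s <- rw[rw$tree_id == tm$tree_id, , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    if (nrow(s) == 0L) { dropped <- c(dropped, tm$tree_id); next }
    cohort <- as.character(assign_cohort(s$year[1L]))
    if (cohort == "Excluded") { dropped <- c(dropped, tm$tree_id); next }
    win <- windows[[cohort]]
    dbh <- reconstruct_dbh(s, tm$census_dbh_cm, tm$census_year)

    ok <- is.finite(s$width_mm) & s$width_mm > 0
    w <- ifelse(ok, s$width_mm, NA_real_)
    lg <- log(w)
    n <- length(lg)
    keep <- rep(FALSE, n)
    if (n >= 3L) {
      idx <- 3:n
      keep[idx] <- !is.na(lg[idx]) & !is.na(lg[idx - 1L]) & !is.na(lg[idx - 2L])
    }
    keep <- keep & s$year >= win[1L] & s$year <= win[2L]
    # DBH entering year t = end-of-year t-1 diameter
    dbh_prev <- c(NA_real_, dbh$dbh_cm[-n])
    keep <- keep & !is.na(dbh_prev)
    if (!any(keep)) { dropped <- c(dropped, tm$tree_id); next }
    k <- which(keep)
    rows[[i]] <- data.frame(
      tree_id = tm$tree_id, site_id = tm$site_id,
      year = s$year[k],
      cohort = cohort, structure = tm$structure,
      log_growth = lg[k],
      lag1_log_growth = lg[k - 1L],
      lag2_log_growth = lg[k - 2L],
      dbh = dbh_prev[k])
  }
  obs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(obs))
    stop("no valid observations assembled")
  if (length(dropped) && !quiet)
    message("excluded ", length(dropped), " trees with no valid rows: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  m <- merge(obs, annual[c("site_id", "year", "wy_precip", "june_tmax")],
             by = c("site_id", "year"), sort = FALSE)
  lost <- nrow(obs) - nrow(m)
  if (lost > 0 && !quiet)
    message("dropped ", lost, " tree-years without complete annual climate")
  m$cohort <- factor(m$cohort, levels = c("Past", "Modern"))
  m$structure <- factor(m$structure, levels = c("savanna", "forest"))
  m <- m[order(m$tree_id, m$year), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("growth_observations", "data.frame")
  m
}

#' Label cohort or cohort-by-structure groups
#'
#' The growth and isotope models are fitted twice: once with random slopes
#' varying by cohort only (two groups) and once by the four cohort-structure
#' combinations.
#'
#' @param obs Observation table carrying `cohort` and `structure`.
#' @param scheme `"cohort-structure"` (4 groups) or `"cohort"` (2 groups).
#' @return `obs` with a `group` factor column.
#' @export
make_groups <- function(obs, scheme = c("cohort-structure", "cohort")) {
  scheme <- match.arg(scheme)
  if (scheme == "cohort") {
    obs$group <- factor(as.character(obs$cohort),
                        levels = c("Past", "Modern"))
  } else {
    st <- as.character(obs$structure)
    st <- paste0(toupper(substr(st, 1, 1)), substr(st, 2, nchar(st)))
    lab <- paste(as.character(obs$cohort), st, sep = "-")
    obs$group <- factor(lab, levels = c("Past-Savanna", "Past-Forest",
                                        "Modern-Savanna", "Modern-Forest"))
  }
  obs$group <- droplevels(obs$group)
  obs
}
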