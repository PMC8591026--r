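#' Read a Tucson-format (decadal) ring-width file
#'
#' Parses the classic dendrochronology interchange layout: one series per
#' block of lines, each line holding a series id (columns 1--8), the decade
#' year of the first value, and up to ten ring widths, with an end-of-series
#' sentinel of `999` (hundredths of a millimetre) or `-9999` (thousandths of
#' a millimetre). The sentinel also identifies the unit convention; this can
#' be overridden when a file uses a non-standard pairing.
#'
#' @param path Path to a `.rwl` file.
#' @param site_id Site label attached to every series; defaults to the file
#'   name without extension.
#' @param units `"auto"` (infer from the sentinel), `"0.01"` or `"0.001"`
#'   millimetres per recorded integer unit.
#' @param quiet Suppress the row-count message.
#' @return A data frame with columns `tree_id`, `site_id`, `year`,
#'   `width_mm`, ordered by series and year. Years within a series are
#'   strictly consecutive; negative widths are rejected.
#' @seealso [write_rwl()], [read_ring_csv()]
#' @export
read_rwl <- function(path, site_id = NULL, units = c("auto", "0.01", "0.001"),
                     quiet = FALSE) {
  units <- match.arg(units)
  if (is.null(site_id)) site_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty ring-width file: ", path)
    return(data.frame(tree_id = character(), site_id = character(),
                      year = integer(), width_mm = numeric()))
  }

  ids <- trimws(substr(lines, 1L, 8L))
  rest <- substr(lines, 9L, nchar(lines))
  toks <- strsplit(trimws(rest), "\\s+")

  series <- list()
  for (id in unique(ids)) {
    sel <- which(ids == id)
    years <- integer(0)
    vals <- integer(0)
    sentinel <- NA_integer_
    prev_end <- NA_integer_
    for (li in sel) {
      tk <- toks[[li]]
      if (length(tk) < 2L)
        stop("malformed line ", li, " in ", path, ": expected year and values")
      v <- suppressWarnings(as.integer(tk))
      if (anyNA(v))
        stop("non-numeric field on line ", li, " in ", path)
      decade <- v[1L]
      vv <- v[-1L]
      stop_idx <- which(vv == 999L | vv == -9999L)
      if (length(stop_idx)) {
        sentinel <- vv[stop_idx[1L]]
        vv <- vv[seq_len(stop_idx[1L] - 1L)]
      }
      if (!is.na(prev_end) && decade != prev_end)
        stop("non-consecutive decade rows for series '", id, "' at line ", li,
             " in ", path, ": expected year ", prev_end, ", found ", decade)
      years <- c(years, decade + seq_along(vv) - 1L)
      vals <- c(vals, vv)
      prev_end <- decade + length(vv)
      if (length(stop_idx)) break
    }
    if (length(sel) && is.na(sentinel))
      stop("series '", id, "' in ", path,
           " has no end-of-series sentinel (999 or -9999)")
    div <- switch(units,
                  "0.01" = 100,
                  "0.001" = 1000,
                  auto = if (sentinel == 999L) 100 else 1000)
    w <- vals / div
    if (any(w < 0))
      stop("negative ring width in series '", id, "' in ", path)
    series[[id]] <- data.frame(tree_id = id, site_id = site_id,
                               year = years, width_mm = w)
  }
  out <- do.call(rbind, c(series, list(make.row.names = FALSE)))
  if (!quiet)
    message("read ", length(series), " series, ", nrow(out), " rings from ",
            basename(path))
  out
}

#' Write ring widths to a Tucson-format (decadal) file
#'
#' The inverse of [read_rwl()]. Widths are recorded as integers in the chosen
#' unit (hundredths of a millimetre by default, sentinel 999; thousandths
#' with sentinel -9999). Widths that are not exact multiples of the unit are
#' rounded.
#'
#' @param rw Data frame with `tree_id`, `year`, `width_mm` (as returned by
#'   [read_rwl()]); years must be consecutive within each series.
#' @param path Output path.
#' @param units `"0.01"` or `"0.001"` mm per integer unit.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rw, path, units = c("0.01", "0.001")) {
  units <- match.arg(units)
  mult <- if (units == "0.01") 100 else 1000
  sentinel <- if (units == "0.01") "999" else "-9999"
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(rw$tree_id)) {
    s <- rw[rw$tree_id == id, , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    if (nrow(s) > 1L && any(diff(s$year) != 1L))
      stop("series '", id, "' has non-consecutive years; cannot write")
    vals <- c(formatC(round(s$width_mm * mult), format = "d"), sentinel)
    years <- c(s$year, s$year[nrow(s)] + 1L)
    decades <- years
    first <- TRUE
    while (length(vals)) {
      y0 <- decades[1L]
      # rows break at decade boundaries after the first (possibly short) row
      n_take <- if (first) min(10L - (y0 %% 10L), length(vals))
                else min(10L, length(vals))
      row_vals <- vals[seq_len(n_take)]
      writeLines(sprintf("%-8s%4d%s", substr(id, 1L, 8L), y0,
                         paste0(sprintf("%6s", row_vals), collapse = "")),
                 con)
      vals <- vals[-seq_len(n_take)]
      decades <- decades[-seq_len(n_take)]
      first <- FALSE
    }
  }
  invisible(path)
}

#' Read or write tidy ring-width CSV
#'
#' Long-format interchange: one row per measured ring with columns
#' `tree_id`, `site_id`, `year`, `width_mm`.
#'
#' @param path CSV path.
#' @param quiet Suppress the row-count message.
#' @return `read_ring_csv()`: a validated data frame; `write_ring_csv()`:
#'   `path`, invisibly.
#' @export
read_ring_csv <- function(path, quiet = FALSE) {
  rw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "site_id", "year", "width_mm")
  if (!all(need %in% names(rw)))
    stop("ring-width CSV must have columns ", paste(need, collapse = ", "))
  if (any(is.finite(rw$width_mm) & rw$width_mm < 0))
    stop("negative ring widths in ", path)
  if (!quiet) message("read ", nrow(rw), " rings from ", basename(path))
  rw[need]
}

#' @rdname read_ring_csv
#' @param rw Ring-width data frame.
#' @export
write_ring_csv <- function(rw, path) {
  utils::write.csv(rw[c("tree_id", "site_id", "year", "width_mm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Average multiple cores of the same tree by year
#'
#' Cores are conventionally labelled by appending a letter to the tree id
#' (e.g. `MOU012A`, `MOU012B`). Same-tree cores are averaged per year before
#' modelling, a common treatment when 1--3 cores per tree were measured.
#'
#' @param rw Ring-width data frame.
#' @param core_pattern Regular expression stripped from `tree_id` to obtain
#'   the tree label; default removes one trailing letter.
#' @return Ring-width data frame with one series per tree.
#' @export
average_cores <- function(rw, core_pattern = "[A-Za-z]$") {
  d <- data.frame(tree_id = sub(core_pattern, "", rw$tree_id),
                  site_id = rw$site_id, year = rw$year,
                  width_mm = rw$width_mm)
  agg <- stats::aggregate(width_mm ~ tree_id + site_id + year, data = d,
                          FUN = mean)
  agg <- agg[order(agg$tree_id, agg$year),
             c("tree_id", "site_id", "year", "width_mm")]
  rownames(agg) <- NULL
  agg
}
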