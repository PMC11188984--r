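# Occurrence-record conditioning: temporal/precision/basis filters, seasonal
# splitting, per-cell thinning, buffered background sampling and covariate
# extraction. An occurrence set is a data.frame with columns
# lon, lat, year, month, precision_m, basis, subspecies, source.

#' Read / write occurrence CSV files
#'
#' Column schema: `lon,lat,year,month,precision_m,basis,subspecies,source`.
#'
#' @param path CSV path.
#' @return data.frame occurrence set.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("lon", "lat", "year", "month", "precision_m", "basis",
              "subspecies", "source")
  miss <- setdiff(needed, names(occ))
  if (length(miss)) stop("occurrence CSV missing columns: ", paste(miss, collapse = ", "))
  occ
}

#' @rdname read_occurrences
#' @param occ Occurrence data.frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' Filter occurrence records by era, precision, basis and longitude
#'
#' Retains records with `min_year <= year <= max_year`, spatial precision at or
#' below `max_precision_m` (records with missing precision are dropped — the
#' conservative reading), basis not `"fossil"`, and longitude strictly west of
#' `lon_max` (spatial outliers east of the cutoff are removed). Any bound left
#' `NULL` is not applied (the fossil filter always applies). Idempotent; the
#' result carries a `filter_log` attribute with in/out counts.
#'
#' @param occ Occurrence data.frame.
#' @param min_year,max_year Year bounds (inclusive), or NULL.
#' @param max_precision_m Precision cap in meters, or NULL.
#' @param lon_max Longitude cutoff: records with `lon > lon_max` are dropped
#'   (NULL to skip).
#' @return Filtered occurrence data.frame.
#' @export
filter_records <- function(occ, min_year = NULL, max_year = NULL,
                           max_precision_m = NULL, lon_max = NULL) {
  if (!is.null(min_year) && !is.null(max_year) && min_year > max_year)
    stop("min_year > max_year")
  n_in <- nrow(occ)
  keep <- rep(TRUE, n_in)
  if (!is.null(min_year)) keep <- keep & !is.na(occ$year) & occ$year >= min_year
  if (!is.null(max_year)) keep <- keep & !is.na(occ$year) & occ$year <= max_year
  if (!is.null(max_precision_m))
    keep <- keep & !is.na(occ$precision_m) & occ$precision_m <= max_precision_m
  keep <- keep & occ$basis != "fossil"
  if (!is.null(lon_max)) keep <- keep & occ$lon <= lon_max
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(n_in = n_in, n_out = nrow(out))
  out
}

#' Split occurrences into winter and summer seasons
#'
#' Winter spans November-February (months 11, 12, 1, 2); summer May-September
#' (5-9). March, April and October — the typical migration months — fall in
#' neither season. Records with missing month are dropped with a warning.
#'
#' @param occ Occurrence data.frame.
#' @return List with elements `winter`, `summer`, `excluded`.
#' @export
split_seasons <- function(occ) {
  if (any(is.na(occ$month))) {
    warning(sum(is.na(occ$month)), " record(s) with missing month dropped")
    occ <- occ[!is.na(occ$month), , drop = FALSE]
  }
  winter_months <- c(11, 12, 1, 2)
  summer_months <- 5:9
  list(winter = occ[occ$month %in% winter_months, , drop = FALSE],
       summer = occ[occ$month %in% summer_months, , drop = FALSE],
       excluded = occ[occ$month %in% c(3, 4, 10), , drop = FALSE])
}

#' Thin occurrences to a single record per raster cell
#'
#' Deterministic: the record with the lowest input index in each cell is kept.
#' Records falling outside the template grid are dropped.
#'
#' @param occ Occurrence data.frame.
#' @param template A `pg_grid`.
#' @return Thinned occurrence data.frame.
#' @export
thin_to_cell <- function(occ, template) {
  if (nrow(occ) == 0) return(occ)
  rc <- xy_to_rowcol(template, occ$lon, occ$lat)
  cell <- (rc$col - 1L) * template$n_rows + rc$row
  keep_idx <- which(!is.na(cell))
  keep_idx <- keep_idx[!duplicated(cell[keep_idx])]
  out <- occ[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample background points within a buffer around presences
#'
#' Uniform over the union of disks of radius `buffer_km` around the presences,
#' intersected with valid cells of the template raster (cells where `valid` is
#' non-NA). Sampling is cell-level uniform with within-cell jitter.
#'
#' @param presences Occurrence data.frame (needs lon/lat).
#' @param template A `pg_grid`.
#' @param valid Optional `pg_raster` whose NA cells are excluded.
#' @param buffer_km Buffer radius in km (default 25).
#' @param n Number of background points (default = number of presences).
#' @param seed Integer seed.
#' @return data.frame with columns `lon`, `lat`.
#' @export
sample_background <- function(presences, template, valid = NULL, buffer_km = 25,
                              n = nrow(presences), seed = 1L) {
  if (nrow(presences) == 0) stop("at least one presence required")
  cc <- cell_centers(template)
  d <- FNN::get.knnx(cbind(presences$lon, presences$lat),
                     cbind(cc$x, cc$y), k = 1)$nn.dist[, 1]
  ok <- d <= buffer_km * 1000
  if (!is.null(valid)) ok <- ok & !is.na(as.vector(valid$values))
  cells <- which(ok)
  if (length(cells) == 0) stop("buffer contains no valid cells")
  set.seed(seed)
  pick <- cells[sample.int(length(cells), n, replace = TRUE)]
  data.frame(
    lon = cc$x[pick] + stats::runif(n, -0.5, 0.5) * template$cell_size,
    lat = cc$y[pick] + stats::runif(n, -0.5, 0.5) * template$cell_size)
}

#' Extract covariate values at points into a labeled sample table
#'
#' Each row holds the stack's layer values at the point's cell. With
#' `month_matched = TRUE`, variables listed in `monthly_vars` are read from the
#' layer of the point's own month (layers named `<var>_01 .. <var>_12`) into a
#' column named `<var>`. Rows hitting nodata in any covariate are dropped and
#' counted in the `drop_log` attribute.
#'
#' @param points data.frame with `lon`, `lat` and (if month-matched) `month`;
#'   an optional `label` column is carried through.
#' @param stack A `pg_stack`.
#' @param label Label for all rows (`"presence"`/`"background"`), used when
#'   `points` has no label column.
#' @param month_matched Use month-matched extraction for `monthly_vars`.
#' @param monthly_vars Monthly variable prefixes, default `c("tmin", "tmax")`.
#' @param months Optional month vector overriding `points$month` (used to
#'   assign season-months to background points).
#' @return A sample table: data.frame with `point_id`, `label`, `lon`, `lat`,
#'   `month` (if available) and one column per covariate.
#' @export
extract_covariates <- function(points, stack, label = "presence",
                               month_matched = FALSE,
                               monthly_vars = c("tmin", "tmax"), months = NULL) {
  g <- stack_grid(stack)
  rc <- xy_to_rowcol(g, points$lon, points$lat)
  if (any(is.na(rc$row))) stop("point outside grid")
  idx <- cbind(rc$row, rc$col)
  lab <- if ("label" %in% names(points)) points$label else rep(label, nrow(points))
  mth <- if (!is.null(months)) months else points$month

  monthly_layers <- grep("_(0[1-9]|1[0-2])$", names(stack), value = TRUE)
  plain_layers <- setdiff(names(stack), monthly_layers)
  cov <- list()
  if (month_matched) {
    if (is.null(mth)) stop("month-matched extraction requires point months")
    for (v in monthly_vars) {
      vals <- rep(NA_real_, nrow(points))
      for (m in sort(unique(mth))) {
        lname <- sprintf("%s_%02d", v, m)
        if (!lname %in% names(stack)) stop("stack lacks monthly layer ", lname)
        sel <- which(mth == m)
        vals[sel] <- stack[[lname]]$values[idx[sel, , drop = FALSE]]
      }
      cov[[v]] <- vals
    }
  }
  for (l in plain_layers) cov[[l]] <- stack[[l]]$values[idx]
  tab <- data.frame(point_id = seq_len(nrow(points)), label = lab,
                    lon = points$lon, lat = points$lat)
  tab$month <- if (!is.null(mth)) mth else NA_integer_
  tab <- cbind(tab, as.data.frame(cov))
  covcols <- names(cov)
  ok <- stats::complete.cases(tab[, covcols, drop = FALSE])
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- c(dropped_nodata = sum(!ok))
  attr(out, "covariates") <- covcols
  out
}

#' Covariate column names of a sample table
#' @param table A sample table from [extract_covariates()].
#' @return Character vector of covariate columns.
#' @export
sample_covariates <- function(table) {
  cv <- attr(table, "covariates")
  if (!is.null(cv)) return(cv)
  setdiff(names(table), c("point_id", "label", "lon", "lat", "month"))
}

#' Assemble the niche-reduction (historical era) occurrence set
#'
#' Historical records (`year <= era_cutoff`) plus a configurable number of
#' post-cutoff records carrying a designated subspecies tag — the arid-adapted
#' supplement that widens the sampled climatic niche.
#'
#' @param occ Occurrence data.frame.
#' @param era_cutoff Last historical year (default 1950).
#' @param supplement_tag Subspecies tag of supplemental records.
#' @param n_supplement Number of supplemental records drawn at random
#'   (default 20).
#' @param seed Integer seed.
#' @return Occurrence data.frame.
#' @export
historical_set <- function(occ, era_cutoff = 1950, supplement_tag = "sonoran",
                           n_supplement = 20, seed = 1L) {
  hist <- occ[!is.na(occ$year) & occ$year <= era_cutoff, , drop = FALSE]
  pool <- occ[!is.na(occ$year) & occ$year > era_cutoff &
                occ$subspecies == supplement_tag, , drop = FALSE]
  if (nrow(pool) > 0 && n_supplement > 0) {
    set.seed(seed)
    take <- pool[sample.int(nrow(pool), min(n_supplement, nrow(pool))), , drop = FALSE]
    hist <- rbind(hist, take)
  }
  rownames(hist) <- NULL
  hist
}
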