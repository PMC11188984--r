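# Binarization at occurrence percentiles, climate clipping, 0-3 consensus
# summation, conflict masking and area accounting.

#' Threshold a suitability surface at an occurrence percentile
#'
#' The threshold is the `(1 - retained_fraction)` type-1 (lower-interpolation)
#' quantile of the surface values at the occurrence points, so at least
#' `retained_fraction` of the occurrence values are >= threshold, exactly.
#'
#' @param surface Suitability `pg_raster`.
#' @param points data.frame with lon/lat (>= 10 on valid cells).
#' @param retained_fraction Fraction of occurrences to retain, in (0, 1].
#' @return List: `threshold` (number), `binary` (`binary_map` pg_raster of
#'   0/1 with `provenance` attribute).
#' @export
threshold_at_occurrences <- function(surface, points, retained_fraction) {
  stopifnot(retained_fraction > 0, retained_fraction <= 1)
  v <- raster_at(surface, points$lon, points$lat)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("all points on nodata")
  if (length(v) < 10) stop("need >= 10 points on valid cells")
  thr <- unname(stats::quantile(v, probs = 1 - retained_fraction, type = 1))
  b <- pg_raster(surface$grid, (surface$values >= thr) * 1)
  attr(b, "provenance") <- list(threshold = thr, retained_fraction = retained_fraction)
  class(b) <- c("binary_map", class(b))
  list(threshold = thr, binary = b)
}

.check_aligned <- function(a, b) {
  if (!grids_aligned(a$grid, b$grid)) stop("misaligned grids")
}

#' Clip a habitat binary to a climate binary (cellwise AND)
#' @param habitat,climate Aligned 0/1 `pg_raster`s.
#' @return 0/1 `pg_raster` (nodata where either input is nodata).
#' @export
clip_to_climate <- function(habitat, climate) {
  .check_aligned(habitat, climate)
  out <- pg_raster(habitat$grid, (habitat$values != 0 & climate$values != 0) * 1)
  class(out) <- c("binary_map", class(out))
  out
}

#' Sum binary habitat maps into a consensus map
#'
#' Cellwise integer sum over the binaries (0..n); nodata wherever any input is
#' nodata. Three binaries is the standard configuration.
#'
#' @param binaries List of aligned 0/1 `pg_raster`s.
#' @return `consensus_map` pg_raster with values 0..length(binaries).
#' @export
consensus_sum <- function(binaries) {
  stopifnot(length(binaries) >= 1)
  g <- binaries[[1]]$grid
  acc <- 0
  for (b in binaries) {
    .check_aligned(binaries[[1]], b)
    acc <- acc + (b$values != 0) * 1
  }
  out <- pg_raster(g, acc)
  attr(out, "n_inputs") <- length(binaries)
  class(out) <- c("consensus_map", class(out))
  out
}

#' Zero consensus cells under a conflict mask
#'
#' Sets the consensus value to 0 wherever the conflict binary is 1
#' (idempotent); provenance notes the mask.
#'
#' @param consensus A `consensus_map`.
#' @param conflict Aligned 0/1 `pg_raster`.
#' @return Masked `consensus_map`.
#' @export
mask_conflict <- function(consensus, conflict) {
  .check_aligned(consensus, conflict)
  v <- consensus$values
  v[!is.na(conflict$values) & conflict$values != 0] <- 0
  out <- pg_raster(consensus$grid, v)
  attr(out, "n_inputs") <- attr(consensus, "n_inputs")
  attr(out, "masked") <- TRUE
  class(out) <- c("consensus_map", class(out))
  out
}

#' Area by consensus class
#'
#' @param consensus A `consensus_map` (integer values).
#' @param cell_area_km2 Area of one cell in km^2 (> 0); default derived from
#'   the grid cell size (m).
#' @return data.frame: `class`, `cells`, `area_km2`; classes partition the
#'   valid cells, so areas sum to valid-cell count times cell area.
#' @export
area_by_class <- function(consensus, cell_area_km2 = (consensus$grid$cell_size / 1000)^2) {
  stopifnot(cell_area_km2 > 0)
  v <- as.vector(consensus$values)
  v <- v[!is.na(v)]
  tab <- table(factor(v, levels = sort(unique(v))))
  data.frame(class = as.integer(names(tab)), cells = as.integer(tab),
             area_km2 = as.integer(tab) * cell_area_km2, row.names = NULL)
}
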