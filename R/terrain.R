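# Grid-to-grid resampling and the deterministic terrain / proximity transforms
# used to build predictor layers (distances, densities, slope, TPI, cover
# fractions). All math is Euclidean in the working projected CRS.

#' Resample a set of rasters onto a common template grid
#'
#' Supported per-layer methods: `"bilinear"` (continuous layers), `"nearest"`
#' (categorical layers), and `"fraction"` (the proportion of fine source cells
#' with value 1 whose centers fall inside each template cell; the source layer
#' must be a 0/1 indicator). Fraction aggregation renormalizes over valid fine
#' cells; bilinear/nearest emit nodata where the source has nodata in support.
#'
#' @param rasters Named list of `pg_raster` inputs.
#' @param template Target `pg_grid`.
#' @param methods Character vector (recycled or named per layer).
#' @return A `pg_stack` on `template`.
#' @export
align_stack <- function(rasters, template, methods) {
  stopifnot(length(rasters) >= 1, !is.null(names(rasters)))
  if (length(methods) == 1L) methods <- rep(methods, length(rasters))
  if (!is.null(names(methods))) methods <- methods[names(rasters)]
  if (length(methods) != length(rasters)) stop("one method per layer required")
  out <- lapply(seq_along(rasters), function(i) {
    m <- methods[[i]]
    if (!m %in% c("bilinear", "nearest", "fraction")) stop("unknown method: ", m)
    resample_raster(rasters[[i]], template, m)
  })
  names(out) <- names(rasters)
  pg_stack(out)
}

resample_raster <- function(raster, template, method) {
  src <- raster$grid
  # overlap check on extents
  src_xmax <- src$origin_x + src$n_cols * src$cell_size
  src_ymin <- src$origin_y - src$n_rows * src$cell_size
  t_xmax <- template$origin_x + template$n_cols * template$cell_size
  t_ymin <- template$origin_y - template$n_rows * template$cell_size
  if (src$origin_x >= t_xmax || src_xmax <= template$origin_x ||
      src_ymin >= template$origin_y || src$origin_y <= t_ymin)
    stop("raster has zero overlap with template")

  if (method == "fraction") return(fraction_resample(raster, template))

  cc <- cell_centers(template)
  # fractional position in source cell-index space (0-based cell centers)
  fx <- (cc$x - src$origin_x) / src$cell_size - 0.5
  fy <- (src$origin_y - cc$y) / src$cell_size - 0.5
  v <- raster$values
  if (method == "nearest") {
    col <- round(fx) + 1; row <- round(fy) + 1
    ok <- col >= 1 & col <= src$n_cols & row >= 1 & row <= src$n_rows
    out <- rep(NA_real_, nrow(cc))
    out[ok] <- v[cbind(row[ok], col[ok])]
  } else {
    # clamp within half a cell of the center hull so template cells over the
    # source margin still get a value; outside the extent stays nodata
    in_ext <- fx > -0.5 & fx < src$n_cols - 0.5 & fy > -0.5 & fy < src$n_rows - 0.5
    fxc <- pmin(pmax(fx, 0), src$n_cols - 1)
    fyc <- pmin(pmax(fy, 0), src$n_rows - 1)
    c0 <- floor(fxc); r0 <- floor(fyc)
    c0 <- pmin(c0, src$n_cols - 2L); r0 <- pmin(r0, src$n_rows - 2L)
    if (src$n_cols == 1L) c0 <- rep(0, length(fxc))
    if (src$n_rows == 1L) r0 <- rep(0, length(fyc))
    wx <- fxc - c0; wy <- fyc - r0
    g <- function(r, c) v[cbind(pmin(r, src$n_rows - 1) + 1L, pmin(c, src$n_cols - 1) + 1L)]
    out <- (1 - wx) * (1 - wy) * g(r0, c0) + wx * (1 - wy) * g(r0, c0 + 1) +
      (1 - wx) * wy * g(r0 + 1, c0) + wx * wy * g(r0 + 1, c0 + 1)
    out[!in_ext] <- NA_real_
  }
  raster_from_vector(template, out)
}

fraction_resample <- function(raster, template) {
  src <- raster$grid
  cc <- cell_centers(src)
  rc <- xy_to_rowcol(template, cc$x, cc$y)
  v <- as.vector(raster$values)
  keep <- !is.na(rc$row) & !is.na(v)
  idx <- (rc$col[keep] - 1L) * template$n_rows + rc$row[keep]
  n_cell <- template$n_rows * template$n_cols
  hit <- rowsum(as.numeric(v[keep] != 0), idx)
  tot <- rowsum(rep(1, length(idx)), idx)
  out <- rep(NA_real_, n_cell)
  out[as.integer(rownames(hit))] <- hit[, 1] / tot[, 1]
  raster_from_vector(template, out)
}

#' Per-class cover fractions on a template grid
#'
#' Expands a categorical cover raster into one 0/1 indicator per class and
#' aggregates each by the `"fraction"` rule, yielding layers named
#' `frac_<class>` that sum to 1 wherever the source is fully valid.
#'
#' @param cover Categorical `pg_raster` (integer class codes).
#' @param template Target `pg_grid`.
#' @param classes Named integer vector, name = class label, value = code.
#' @return `pg_stack` of fraction layers.
#' @export
cover_fractions <- function(cover, template, classes) {
  layers <- lapply(classes, function(code) {
    ind <- pg_raster(cover$grid, (cover$values == code) * 1)
    ind$values[is.na(cover$values)] <- NA_real_
    fraction_resample(ind, template)
  })
  names(layers) <- paste0("frac_", names(classes))
  pg_stack(layers)
}

# pad a matrix by one ring, linearly extrapolated, so Horn's stencil reduces to
# one-sided differences at edges (a plane keeps its exact slope at the margin)
pad_linear <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  top <- if (nr >= 2) 2 * m[1, ] - m[2, ] else m[1, ]
  bot <- if (nr >= 2) 2 * m[nr, ] - m[nr - 1, ] else m[nr, ]
  m2 <- rbind(top, m, bot)
  left <- if (nc >= 2) 2 * m2[, 1] - m2[, 2] else m2[, 1]
  right <- if (nc >= 2) 2 * m2[, nc] - m2[, nc - 1] else m2[, nc]
  unname(cbind(left, m2, right))
}

#' Slope in degrees from an elevation raster (Horn's 3x3 method)
#'
#' Gradient by Horn's weighted finite differences; edge cells use one-sided
#' differences via linear edge extrapolation. Cells with nodata anywhere in
#' their 3x3 support become nodata.
#'
#' @param elev Elevation `pg_raster`; cell size and values in the same metric
#'   unit (m).
#' @return Slope raster in degrees, in `[0, 90)`.
#' @export
slope_from_elevation <- function(elev) {
  g <- elev$grid
  if (g$n_rows < 3 || g$n_cols < 3) stop("grid smaller than 3x3")
  p <- pad_linear(elev$values)
  nr <- g$n_rows; nc <- g$n_cols
  sh <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sh(0, 0); b <- sh(0, 1); cc_ <- sh(0, 2)
  d <- sh(1, 0);               f <- sh(1, 2)
  gg <- sh(2, 0); hh <- sh(2, 1); ii <- sh(2, 2)
  dzdx <- ((cc_ + 2 * f + ii) - (a + 2 * d + gg)) / (8 * g$cell_size)
  dzdy <- ((gg + 2 * hh + ii) - (a + 2 * b + cc_)) / (8 * g$cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(dzdx) | is.na(dzdy)] <- NA_real_
  pg_raster(g, slope)
}

# offsets (dr, dc, include-center flag applied by caller) within a radius
circle_offsets <- function(radius_cells) {
  r <- floor(radius_cells)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off[sqrt(off$dr^2 + off$dc^2) <= radius_cells + 1e-9, , drop = FALSE]
}

# nodata-aware circular focal mean via offset shifting
focal_mean <- function(values, radius_cells, exclude_center = FALSE) {
  off <- circle_offsets(radius_cells)
  if (exclude_center) off <- off[!(off$dr == 0 & off$dc == 0), , drop = FALSE]
  nr <- nrow(values); nc <- ncol(values)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  valid <- !is.na(values)
  v0 <- values; v0[!valid] <- 0
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    s[rs, cs] <- s[rs, cs] + v0[rs + dr, cs + dc]
    n[rs, cs] <- n[rs, cs] + valid[rs + dr, cs + dc]
  }
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

#' Topographic position index
#'
#' Elevation of each cell minus the mean elevation of its neighbors within
#' `radius` (center excluded). Positive on ridges/peaks, negative in
#' depressions. Focal mean renormalizes over valid neighbors.
#'
#' @param elev Elevation `pg_raster`.
#' @param radius Neighborhood radius in CRS units; must be >= cell size.
#' @return TPI `pg_raster`.
#' @export
tpi <- function(elev, radius) {
  g <- elev$grid
  if (radius < g$cell_size) stop("radius < cell_size")
  m <- focal_mean(elev$values, radius / g$cell_size, exclude_center = TRUE)
  pg_raster(g, elev$values - m)
}

#' Euclidean distance to the nearest feature cell
#'
#' Exact center-to-center Euclidean distance from every cell to the nearest
#' cell flagged 1 in the mask; 0 on feature cells themselves.
#'
#' @param mask `pg_raster` of 0/1 (NA allowed; NA cells get NA output).
#' @return Distance raster in CRS units.
#' @export
distance_to_features <- function(mask) {
  g <- mask$grid
  v <- as.vector(mask$values)
  feat <- which(!is.na(v) & v != 0)
  if (length(feat) == 0L) stop("empty mask: no feature cells")
  cc <- cell_centers(g)
  d <- FNN::get.knnx(cbind(cc$x[feat], cc$y[feat]), cbind(cc$x, cc$y), k = 1)$nn.dist[, 1]
  d[is.na(v)] <- NA_real_
  raster_from_vector(g, d)
}

#' Fraction of flagged cells within a circular window
#'
#' A unitless density in `[0, 1]`: the proportion of cells with mask value 1
#' inside a circular window of the given radius (center included), normalized
#' over valid cells.
#'
#' @param mask `pg_raster` of 0/1.
#' @param radius Window radius in CRS units; must be >= cell size.
#' @return Density `pg_raster`.
#' @export
focal_density <- function(mask, radius) {
  g <- mask$grid
  if (radius < g$cell_size) stop("radius < cell_size")
  m <- focal_mean((mask$values != 0) * 1 + 0 * mask$values, radius / g$cell_size)
  pg_raster(g, m)
}
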