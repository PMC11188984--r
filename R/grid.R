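#' Regular raster grid geometry
#'
#' A `pg_grid` describes the geometry shared by every layer of an analysis:
#' number of rows/columns, square cell size, and the coordinates of the
#' *outer corner* of the top-left cell. Cell-center registration is used
#' throughout: row 1 is the north edge, and the center of cell (r, c) is at
#' `x = origin_x + (c - 0.5) * cell_size`, `y = origin_y - (r - 0.5) * cell_size`.
#' All distances are Euclidean in the working (projected, equal-area) CRS.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Side length of a (square) cell, in CRS units (m).
#' @param origin_x,origin_y Coordinates of the outer corner of the top-left cell.
#' @param crs Free-text CRS identifier; informational only.
#' @param nodata Sentinel value used when writing rasters to disk. In memory
#'   nodata cells are `NA`.
#' @return An object of class `pg_grid`.
#' @export
pg_grid <- function(n_rows, n_cols, cell_size = 1, origin_x = 0,
                    origin_y = n_rows * cell_size, crs = "local-equal-area",
                    nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
                 crs = as.character(crs), nodata = as.numeric(nodata)),
            class = "pg_grid")
}

#' @export
print.pg_grid <- function(x, ...) {
  cat(sprintf("<pg_grid %d x %d, cell %g, origin (%g, %g), crs '%s'>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' Test whether two grids share identical geometry
#' @param a,b `pg_grid` objects.
#' @return `TRUE` iff all geometry fields match (tolerance 1e-9 on reals).
#' @export
grids_aligned <- function(a, b) {
  isTRUE(a$n_rows == b$n_rows) && isTRUE(a$n_cols == b$n_cols) &&
    isTRUE(abs(a$cell_size - b$cell_size) < 1e-9) &&
    isTRUE(abs(a$origin_x - b$origin_x) < 1e-9) &&
    isTRUE(abs(a$origin_y - b$origin_y) < 1e-9) &&
    identical(a$crs, b$crs)
}

#' Raster: a grid plus a value matrix
#'
#' @param grid A `pg_grid`.
#' @param values Numeric matrix of dimension `n_rows x n_cols` (row 1 = north),
#'   or a single number to fill. `NA` marks nodata.
#' @return An object of class `pg_raster`.
#' @export
pg_raster <- function(grid, values) {
  stopifnot(inherits(grid, "pg_grid"))
  if (length(values) == 1L) values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values shape must equal (n_rows, n_cols)")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "pg_raster")
}

#' @export
print.pg_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  rng <- if (length(v)) sprintf("[%g, %g]", min(v), max(v)) else "[all nodata]"
  cat(sprintf("<pg_raster %d x %d, values %s, %d nodata>\n", x$grid$n_rows,
              x$grid$n_cols, rng, sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of every cell (column-major order, matching
#' `as.vector` on the value matrix)
#' @param grid A `pg_grid`.
#' @return data.frame with columns row, col, x, y.
#' @export
cell_centers <- function(grid) {
  rc <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  data.frame(row = rc$row, col = rc$col,
             x = grid$origin_x + (rc$col - 0.5) * grid$cell_size,
             y = grid$origin_y - (rc$row - 0.5) * grid$cell_size)
}

#' Map x/y coordinates to row/col indices
#' @param grid A `pg_grid`.
#' @param x,y Coordinate vectors.
#' @return data.frame with columns row, col; NA for points outside the grid.
#' @export
xy_to_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point coordinates
#' @param raster A `pg_raster`.
#' @param x,y Coordinates.
#' @return Numeric vector; NA outside the grid or on nodata cells.
#' @export
raster_at <- function(raster, x, y) {
  rc <- xy_to_rowcol(raster$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- raster$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Raster stack: named, aligned layers
#'
#' @param ... Named `pg_raster` layers, or a single named list of them.
#' @return An object of class `pg_stack` (a named list with a `grid` attribute).
#' @export
pg_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && !inherits(layers[[1]], "pg_raster"))
    layers <- layers[[1]]
  if (is.null(names(layers)) || any(names(layers) == "") || anyDuplicated(names(layers)))
    stop("stack layers must have unique non-empty names")
  if (!all(vapply(layers, inherits, TRUE, "pg_raster")))
    stop("all stack elements must be pg_raster")
  g <- layers[[1]]$grid
  for (l in layers) if (!grids_aligned(g, l$grid)) stop("stack layers are not aligned")
  structure(layers, grid = g, class = "pg_stack")
}

#' @export
print.pg_stack <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<pg_stack %d layers on %d x %d grid: %s>\n", length(x),
              g$n_rows, g$n_cols, paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Grid of a stack
#' @param stack A `pg_stack`.
#' @return The shared `pg_grid`.
#' @export
stack_grid <- function(stack) attr(stack, "grid")

#' Flatten a stack to a cells-by-layers matrix (column-major cell order)
#' @param stack A `pg_stack`.
#' @return Numeric matrix, one column per layer.
#' @export
stack_matrix <- function(stack) {
  do.call(cbind, lapply(stack, function(r) as.vector(r$values)))
}

#' Rebuild a raster from a flat cell vector (column-major order as produced by
#' [stack_matrix()]/`as.vector` on the value matrix)
#' @param grid A `pg_grid`.
#' @param v Numeric vector of length n_rows * n_cols.
#' @return A `pg_raster`.
#' @export
raster_from_vector <- function(grid, v) {
  pg_raster(grid, matrix(v, grid$n_rows, grid$n_cols))
}
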