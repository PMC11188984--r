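# Minimal single-band float32 GeoTIFF I/O.
#
# The on-disk format is an uncompressed little-endian baseline TIFF with the
# GeoTIFF ModelPixelScale / ModelTiepoint tags and the GDAL_NODATA ASCII tag,
# which is what mainstream GIS tools emit for simple single-band rasters and
# what they will read back. Only what this package writes is guaranteed to be
# readable: single band, 32-bit IEEE float, compression "none", strip layout.

.tif_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L,
                SBYTE = 6L, UNDEF = 7L, SSHORT = 8L, SLONG = 9L,
                SRATIONAL = 10L, FLOAT = 11L, DOUBLE = 12L)
.tif_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Write a raster as a single-band float32 GeoTIFF
#'
#' Nodata cells (`NA`) are stored as the grid's `nodata` sentinel and declared
#' in the GDAL_NODATA tag; grid geometry goes into the ModelPixelScale and
#' ModelTiepoint tags and the CRS text into ImageDescription.
#'
#' @param raster A `pg_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(raster, path) {
  stopifnot(inherits(raster, "pg_raster"))
  g <- raster$grid
  w <- g$n_cols; h <- g$n_rows
  v <- raster$values
  v[is.na(v)] <- g$nodata
  pix <- as.vector(t(v))                      # row-major, top row first

  nodata_str <- paste0(format(g$nodata, scientific = FALSE), rawToChar(as.raw(0)))
  desc_str <- paste0("crs=", g$crs, rawToChar(as.raw(0)))
  scale <- c(g$cell_size, g$cell_size, 0)
  tie <- c(0, 0, 0, g$origin_x, g$origin_y, 0)

  data_off <- 8L
  n_pix_bytes <- 4L * w * h
  ifd_off <- data_off + n_pix_bytes

  # tag, type, count, value (inline numeric or deferred payload)
  tags <- list(
    list(256L, "LONG", 1L, w),
    list(257L, "LONG", 1L, h),
    list(258L, "SHORT", 1L, 32L),
    list(259L, "SHORT", 1L, 1L),
    list(262L, "SHORT", 1L, 1L),
    list(270L, "ASCII", nchar(desc_str), charToRaw(desc_str)),
    list(273L, "LONG", 1L, data_off),
    list(277L, "SHORT", 1L, 1L),
    list(278L, "LONG", 1L, h),
    list(279L, "LONG", 1L, n_pix_bytes),
    list(339L, "SHORT", 1L, 3L),
    list(33550L, "DOUBLE", 3L, scale),
    list(33922L, "DOUBLE", 6L, tie),
    list(42113L, "ASCII", nchar(nodata_str), charToRaw(nodata_str))
  )
  n_tag <- length(tags)
  ext_off <- ifd_off + 2L + 12L * n_tag + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(pix, con, size = 4, endian = "little")  # float32 pixels

  writeBin(n_tag, con, size = 2, endian = "little")
  ext_payload <- list()
  cur_ext <- ext_off
  for (tg in tags) {
    type_id <- .tif_types[[tg[[2]]]]
    sz <- .tif_type_size[type_id] * tg[[3]]
    writeBin(tg[[1]], con, size = 2, endian = "little")
    writeBin(as.integer(type_id), con, size = 2, endian = "little")
    writeBin(as.integer(tg[[3]]), con, size = 4, endian = "little")
    val <- tg[[4]]
    if (sz <= 4L) {
      if (is.raw(val)) {
        pad <- c(val, raw(4L - length(val)))
        writeBin(pad, con)
      } else if (type_id == 3L) {       # SHORT inline: low 2 bytes
        writeBin(as.integer(val), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(val), con, size = 4, endian = "little")
      }
    } else {
      writeBin(as.integer(cur_ext), con, size = 4, endian = "little")
      ext_payload <- c(ext_payload, list(list(type_id, val)))
      cur_ext <- cur_ext + sz + (sz %% 2L)
    }
  }
  writeBin(0L, con, size = 4, endian = "little")   # next IFD: none
  for (p in ext_payload) {
    if (is.raw(p[[2]])) {
      bytes <- p[[2]]
      writeBin(bytes, con)
      if (length(bytes) %% 2L) writeBin(raw(1), con)
    } else if (p[[1]] == 12L) {
      writeBin(as.numeric(p[[2]]), con, size = 8, endian = "little")
    } else {
      writeBin(as.integer(p[[2]]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

.read_tif_values <- function(con, type_id, count, inline_raw) {
  sz <- .tif_type_size[type_id] * count
  if (sz > 4L) {
    off <- readBin(inline_raw, "integer", 1, size = 4, endian = "little")
    seek(con, off)
    bytes <- readBin(con, "raw", sz)
  } else bytes <- inline_raw[seq_len(sz)]
  switch(as.character(type_id),
    "2" = rawToChar(bytes[bytes != as.raw(0)]),
    "3" = readBin(bytes, "integer", count, size = 2, signed = FALSE, endian = "little"),
    "4" = readBin(bytes, "integer", count, size = 4, endian = "little"),
    "11" = readBin(bytes, "numeric", count, size = 4, endian = "little"),
    "12" = readBin(bytes, "numeric", count, size = 8, endian = "little"),
    bytes)
}

#' Read a single-band float32 GeoTIFF written by [write_geotiff()]
#'
#' @param path File path.
#' @param default_crs CRS identifier assumed (with a warning) when the file
#'   carries no CRS text.
#' @return A `pg_raster`; sentinel-valued cells become `NA` and the sentinel is
#'   kept on the grid's `nodata` field.
#' @export
read_geotiff <- function(path, default_crs = "local-equal-area") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- rawToChar(readBin(con, "raw", 2))
  if (byte_order != "II") stop("unsupported TIFF byte order (need little-endian)")
  magic <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (magic != 42L) stop("not a TIFF file")
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, ifd_off)
  n_tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  entries <- vector("list", n_tag)
  for (i in seq_len(n_tag)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
    type_id <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
    count <- readBin(con, "integer", 1, size = 4, endian = "little")
    inline <- readBin(con, "raw", 4)
    entries[[i]] <- list(tag = tag, type = type_id, count = count, inline = inline)
  }
  tagval <- function(id, default = NULL) {
    for (e in entries) if (e$tag == id) {
      pos <- seek(con)
      out <- .read_tif_values(con, e$type, e$count, e$inline)
      seek(con, pos)
      return(out)
    }
    default
  }
  w <- tagval(256L); h <- tagval(257L)
  if (is.null(w) || is.null(h)) stop("malformed TIFF: missing dimensions")
  if (!identical(tagval(259L, 1L)[1], 1L)) stop("compressed TIFF not supported")
  if (tagval(258L, 32L)[1] != 32L || tagval(339L, 3L)[1] != 3L)
    stop("only float32 sample format supported")
  offs <- tagval(273L); cnts <- tagval(279L)
  pix <- numeric(0)
  for (i in seq_along(offs)) {
    seek(con, offs[i])
    pix <- c(pix, readBin(con, "numeric", cnts[i] / 4L, size = 4, endian = "little"))
  }
  vals <- matrix(pix, nrow = h, ncol = w, byrow = TRUE)

  scale <- tagval(33550L, c(1, 1, 0))
  tie <- tagval(33922L, c(0, 0, 0, 0, h * scale[2], 0))
  nodata <- suppressWarnings(as.numeric(tagval(42113L, "NA")))
  desc <- tagval(270L, "")
  crs <- if (grepl("^crs=", desc)) sub("^crs=", "", desc) else {
    warning("GeoTIFF carries no CRS; assuming '", default_crs, "'")
    default_crs
  }
  if (is.na(nodata)) nodata <- -9999
  g <- pg_grid(h, w, cell_size = scale[1], origin_x = tie[4], origin_y = tie[5],
               crs = crs, nodata = nodata)
  # float32 sentinel comparison must tolerate the float32 representation
  sent32 <- readBin(writeBin(nodata, raw(), size = 4, endian = "little"),
                    "numeric", 1, size = 4, endian = "little")
  vals[vals == sent32 | vals == nodata] <- NA_real_
  pg_raster(g, vals)
}
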