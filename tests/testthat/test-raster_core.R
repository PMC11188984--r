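# raster grid model, resampling, terrain and proximity transforms, GeoTIFF I/O

test_that("align_stack preserves constants under every method", {
  fine <- pg_grid(8, 8, 1)
  template <- pg_grid(4, 4, 2)
  for (m in c("bilinear", "nearest", "fraction")) {
    const <- if (m == "fraction") 1 else 7.5
    r <- pg_raster(fine, const)
    out <- align_stack(list(a = r), template, m)
    expect_true(all(out$a$values == if (m == "fraction") 1 else const),
                info = m)
  }
  expect_error(align_stack(list(a = pg_raster(fine, 1)), template, "kernel"),
               "unknown method")
  far <- pg_grid(4, 4, 1, origin_x = 1000, origin_y = 1000)
  expect_error(align_stack(list(a = pg_raster(far, 1)), template, "nearest"),
               "zero overlap")
})

test_that("fraction aggregation counts fine cells per class", {
  fine <- pg_grid(2, 2, 1)
  coarse <- pg_grid(1, 1, 2)
  mask <- pg_raster(fine, matrix(c(1, 1, 1, 0), 2, 2))
  out <- align_stack(list(a = mask), coarse, "fraction")
  expect_equal(out$a$values[1, 1], 0.75)
})

test_that("bilinear resampling is the identity at source cell centers", {
  g <- pg_grid(5, 7, 3)
  set.seed(4)
  r <- pg_raster(g, matrix(rnorm(35), 5, 7))
  out <- align_stack(list(a = r), g, "bilinear")
  expect_equal(out$a$values, r$values, tolerance = 1e-12)
})

test_that("cover fractions across classes sum to one on valid cells", {
  fine <- pg_grid(20, 20, 1)
  set.seed(9)
  cover <- pg_raster(fine, matrix(sample(1:4, 400, TRUE), 20, 20))
  coarse <- pg_grid(5, 5, 4)
  fr <- cover_fractions(cover, coarse, c(a = 1, b = 2, c = 3, d = 4))
  total <- Reduce(`+`, lapply(fr, function(r) r$values))
  expect_equal(total, matrix(1, 5, 5), tolerance = 1e-12)
})

test_that("slope matches closed forms and is shift invariant", {
  flat <- pg_raster(pg_grid(6, 6, 1), 3)
  expect_true(all(slope_from_elevation(flat)$values == 0))

  plane45 <- pg_raster(pg_grid(8, 8, 1), outer(1:8, 1:8, function(r, c) c))
  expect_equal(slope_from_elevation(plane45)$values,
               matrix(45, 8, 8), tolerance = 1e-9)

  plane02 <- pg_raster(pg_grid(8, 8, 10), outer(1:8, 1:8, function(r, c) 2 * c))
  expect_equal(slope_from_elevation(plane02)$values[4, 4],
               atan(0.2) * 180 / pi, tolerance = 1e-9)  # 11.3099 degrees

  set.seed(2)
  e <- pg_raster(pg_grid(10, 10, 5), matrix(rnorm(100, 100, 20), 10, 10))
  e_shift <- pg_raster(e$grid, e$values + 123.4)
  expect_equal(slope_from_elevation(e)$values,
               slope_from_elevation(e_shift)$values, tolerance = 1e-9)

  expect_error(slope_from_elevation(pg_raster(pg_grid(2, 2, 1), 0)), "3x3")
})

test_that("tpi matches a brute-force neighborhood oracle", {
  flat <- pg_raster(pg_grid(6, 6, 1), 2)
  expect_true(all(abs(tpi(flat, 1)$values) < 1e-12))

  peak <- pg_raster(pg_grid(5, 5, 1), matrix(0, 5, 5))
  peak$values[3, 3] <- 10
  tp <- tpi(peak, 1)
  expect_gt(tp$values[3, 3], 0)
  expect_lt(tp$values[3, 4], 0)

  set.seed(7)
  e <- pg_raster(pg_grid(3, 3, 1), matrix(rnorm(9), 3, 3))
  tp <- tpi(e, 1)
  # brute force: neighbors within distance 1 (4-neighborhood), center excluded
  for (r in 1:3) for (c in 1:3) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if ((dr != 0 || dc != 0) && sqrt(dr^2 + dc^2) <= 1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= 3 && cc >= 1 && cc <= 3) nb <- c(nb, e$values[rr, cc])
      }
    }
    expect_equal(tp$values[r, c], e$values[r, c] - mean(nb), tolerance = 1e-12)
  }
  expect_error(tpi(e, 0.5), "radius")
})

test_that("distance transform matches brute force on small grids", {
  g <- pg_grid(5, 5, 10)
  m <- pg_raster(g, matrix(0, 5, 5)); m$values[3, 3] <- 1
  d <- distance_to_features(m)
  expect_equal(d$values[3, 3], 0)
  expect_equal(d$values[3, 4], 10)
  expect_equal(d$values[4, 4], sqrt(2) * 10)

  # brute-force oracle on random masks up to 20x20
  for (seed in 1:3) {
    set.seed(seed)
    nr <- sample(5:20, 1); nc <- sample(5:20, 1); cs <- sample(c(1, 30), 1)
    g <- pg_grid(nr, nc, cs)
    mask <- matrix(rbinom(nr * nc, 1, 0.08), nr, nc)
    if (sum(mask) == 0) mask[1, 1] <- 1
    d <- distance_to_features(pg_raster(g, mask))$values
    feats <- which(mask == 1, arr.ind = TRUE)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      brute <- min(sqrt((feats[, 1] - r)^2 + (feats[, 2] - c)^2)) * cs
      expect_equal(d[r, c], brute, tolerance = 1e-9)
    }
    expect_true(all(d[mask == 1] == 0))
  }
  expect_error(distance_to_features(pg_raster(g, matrix(0, nr, nc))), "empty mask")
})

test_that("focal density is a window fraction in [0,1]", {
  g <- pg_grid(7, 7, 1)
  ones <- pg_raster(g, 1)
  expect_equal(focal_density(ones, 2)$values[4, 4], 1)
  zeros <- pg_raster(g, 0)
  expect_true(all(focal_density(zeros, 2)$values == 0))
  single <- pg_raster(g, matrix(0, 7, 7)); single$values[4, 4] <- 1
  # radius = 1 cell: the window holds the center plus 4 neighbors = 5 cells
  expect_equal(focal_density(single, 1)$values[4, 4], 0.2)
  expect_error(focal_density(single, 0.3), "radius")
})

test_that("GeoTIFF round-trips grid, values and nodata", {
  g <- pg_grid(9, 11, 25, origin_x = 1000, origin_y = 5000, crs = "epsg:32610")
  set.seed(5)
  r <- pg_raster(g, matrix(rnorm(99), 9, 11))
  r$values[2, 3] <- NA
  p1 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(r, p1)
  r2 <- read_geotiff(p1)
  expect_true(grids_aligned(r$grid, r2$grid))
  expect_identical(is.na(r2$values), is.na(r$values))
  expect_lt(max(abs(r$values - r2$values), na.rm = TRUE), 1e-6)  # float32
  # second round trip is bit-exact for float32 payloads
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(r2, p2)
  expect_identical(read_geotiff(p2)$values, r2$values)
  expect_error(read_geotiff(file.path(tempdir(), "no_such.tif")), "exist")
})

test_that("misaligned rasters read from disk can be aligned onto one grid", {
  fine <- pg_grid(10, 10, 1)
  coarse <- pg_grid(5, 5, 2)
  set.seed(8)
  a <- pg_raster(fine, matrix(runif(100), 10, 10))
  b <- pg_raster(coarse, matrix(runif(25), 5, 5))
  pa <- withr::local_tempfile(fileext = ".tif")
  pb <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(a, pa); write_geotiff(b, pb)
  st <- align_stack(list(a = read_geotiff(pa), b = read_geotiff(pb)),
                    coarse, c("bilinear", "bilinear"))
  expect_true(grids_aligned(stack_grid(st), coarse))
  expect_equal(st$b$values, b$values, tolerance = 1e-6)
})
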