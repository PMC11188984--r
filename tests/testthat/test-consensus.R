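# thresholding, clipping, consensus summation, masking, area accounting,
# pipeline orchestration

test_that("occurrence-percentile thresholds keep the stated fraction", {
  g <- pg_grid(10, 10, 1)
  surf <- pg_raster(g, matrix(seq(0.01, 1, length.out = 100), 10, 10))
  cc <- cell_centers(g)

  # point values 0.1..1.0: retained 0.8 -> type-1 20th percentile
  vals <- seq(0.1, 1, by = 0.1)
  idx <- vapply(vals, function(v) which.min(abs(as.vector(surf$values) - v)), 0L)
  pts <- data.frame(lon = cc$x[idx], lat = cc$y[idx])
  pv <- raster_at(surf, pts$lon, pts$lat)
  th <- threshold_at_occurrences(surf, pts, 0.8)
  expect_equal(th$threshold, sort(pv)[2])           # lower-interpolation rule
  expect_gte(mean(pv >= th$threshold), 0.8)

  th1 <- threshold_at_occurrences(surf, pts, 1.0)
  expect_equal(th1$threshold, min(pv))
  expect_true(all(pv >= th1$threshold))

  set.seed(18)
  for (f in c(0.85, 0.95, 0.99)) {
    surf_r <- pg_raster(g, matrix(runif(100), 10, 10))
    pick <- sample(100, 40, replace = TRUE)
    pts_r <- data.frame(lon = cc$x[pick], lat = cc$y[pick])
    th_r <- threshold_at_occurrences(surf_r, pts_r, f)
    pv_r <- raster_at(surf_r, pts_r$lon, pts_r$lat)
    expect_gte(mean(pv_r >= th_r$threshold), f)
    expect_true(all(th_r$binary$values %in% c(0, 1)))
  }
  expect_error(threshold_at_occurrences(surf, pts, 0), "retained_fraction")
})

test_that("clip, sum and mask match hand-enumerated 3x3 tables", {
  g <- pg_grid(3, 3, 1)
  h <- pg_raster(g, matrix(c(1, 0, 1, 1, 1, 0, 0, 0, 1), 3, 3))
  cl <- pg_raster(g, matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3, 3))
  expect_equal(clip_to_climate(h, cl)$values, h$values * cl$values)
  expect_equal(clip_to_climate(h, pg_raster(g, 0))$values, matrix(0, 3, 3))
  expect_equal(clip_to_climate(h, pg_raster(g, 1))$values, h$values)

  b1 <- h; b2 <- cl
  b3 <- pg_raster(g, matrix(c(0, 1, 1, 0, 1, 0, 1, 1, 0), 3, 3))
  cs <- consensus_sum(list(b1, b2, b3))
  expect_equal(cs$values, b1$values + b2$values + b3$values)
  expect_true(all(cs$values %in% 0:3))
  expect_equal(consensus_sum(list(b3, b1, b2))$values, cs$values)
  expect_equal(consensus_sum(list(pg_raster(g, 1), pg_raster(g, 1),
                                  pg_raster(g, 1)))$values, matrix(3, 3, 3))

  conf <- pg_raster(g, matrix(c(0, 0, 1, 0, 1, 0, 0, 0, 0), 3, 3))
  masked <- mask_conflict(cs, conf)
  expect_true(all(masked$values[conf$values == 1] == 0))
  expect_equal(masked$values[conf$values == 0], cs$values[conf$values == 0])
  expect_equal(mask_conflict(masked, conf)$values, masked$values)  # idempotent
  expect_equal(mask_conflict(cs, pg_raster(g, 1))$values, matrix(0, 3, 3))
  expect_equal(mask_conflict(cs, pg_raster(g, 0))$values, cs$values)

  g2 <- pg_grid(3, 3, 2)
  expect_error(clip_to_climate(h, pg_raster(g2, 1)), "misaligned")
  expect_error(mask_conflict(cs, pg_raster(g2, 1)), "misaligned")
})

test_that("area accounting conserves total valid area", {
  g <- pg_grid(4, 4, 1000)                      # 1 km cells
  m <- matrix(c(rep(3, 10), rep(2, 3), rep(0, 3)), 4, 4)
  cons <- pg_raster(g, m)
  class(cons) <- c("consensus_map", class(cons))
  at <- area_by_class(cons)
  expect_equal(at$area_km2[at$class == 3], 10)
  expect_equal(sum(at$cells), 16)
  expect_equal(sum(at$area_km2), 16 * 1)
  # hand count on the toy layout
  expect_equal(at$cells, c(3, 3, 10))
})

test_that("clipping before summation never exceeds summing unclipped", {
  set.seed(19)
  g <- pg_grid(6, 6, 1)
  bins <- lapply(1:3, function(i) pg_raster(g, matrix(rbinom(36, 1, 0.5), 6, 6)))
  clim <- pg_raster(g, matrix(rbinom(36, 1, 0.6), 6, 6))
  clipped <- consensus_sum(lapply(bins, clip_to_climate, climate = clim))
  unclipped <- consensus_sum(bins)
  expect_true(all(clipped$values <= unclipped$values))
  # monotonicity: raising one binary cell can only raise the consensus
  bins2 <- bins
  bins2[[2]]$values[3, 3] <- 1
  expect_true(all(consensus_sum(bins2)$values >= consensus_sum(bins)$values))
})

test_that("pipeline stages run and halt where asked", {
  cfg <- default_config(seed = 3, out_dir = withr::local_tempdir())
  cfg$grid <- list(n_rows = 60, n_cols = 60, cell_size = 100)
  cfg$n_occurrences <- 600
  cfg$n_individuals <- 3
  cfg$n_steps <- 120
  cfg$rf_trees <- 40
  cfg$write_geotiffs <- FALSE
  res <- run_pipeline(cfg, stop_after = "prep")
  expect_true(all(c("pack", "occurrences", "tracks", "seasons") %in% names(res)))
  expect_gt(nrow(res$seasons$winter), 0)
  expect_true(file.exists(file.path(cfg$out_dir, "pipeline.log")))
  expect_true(file.exists(file.path(cfg$out_dir, "occurrences.csv")))
})
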