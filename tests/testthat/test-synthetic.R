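# synthetic landscape / occurrence / track / future-climate generators

test_that("gaussian random field honors sill, seed and variance", {
  g <- pg_grid(60, 60, 100)
  expect_equal(gaussian_random_field(g, 3.5, 0, 500, 1)$values,
               matrix(3.5, 60, 60))
  a <- gaussian_random_field(g, 0, 2, 800, seed = 11)
  b <- gaussian_random_field(g, 0, 2, 800, seed = 11)
  expect_identical(a$values, b$values)
  expect_error(gaussian_random_field(g, 0, 1, -5, 1), "range")

  big <- gaussian_random_field(pg_grid(200, 200, 100), 0, 4, 1000, seed = 42)
  expect_lt(abs(var(as.vector(big$values)) - 4) / 4, 0.25)
})

test_that("make_landscape is reproducible with a coherent seasonal cycle", {
  pack <- fixture_pack()
  pack2 <- make_landscape(landscape_truth(master_seed = 101L), pg_grid(60, 60, 100))
  expect_identical(pack$monthly_climate$tmin_01$values,
                   pack2$monthly_climate$tmin_01$values)
  expect_identical(pack$cover_class$values, pack2$cover_class$values)

  winter_min <- mean(pack$monthly_climate$tmin_01$values)
  summer_min <- mean(pack$monthly_climate$tmin_07$values)
  expect_lt(winter_min, summer_min)
  summer_max <- mean(pack$monthly_climate$tmax_07$values)
  expect_gt(summer_max, summer_min)

  prev <- table(pack$cover_class$values) / length(pack$cover_class$values)
  target <- landscape_truth()$cover_prevalence
  expect_true(all(abs(as.numeric(prev) - as.numeric(target)) <= 0.05))

  expect_error(make_landscape(landscape_truth(), pg_grid(30, 30, 100)),
               "too small")
})

test_that("true_suitability is the stated logistic of raw covariates", {
  pack <- fixture_pack()
  covs <- fixture_covs()
  flat <- true_suitability(pack, beta = c(intercept = 0), covariates = covs)
  expect_equal(flat$values, matrix(0.5, 60, 60))

  s <- true_suitability(pack, beta = c(intercept = 0, grass = 2), covariates = covs)
  on_grass <- covs$grass$values == 1
  expect_equal(unique(s$values[on_grass]), plogis(2))   # logistic(2)
  expect_equal(unique(s$values[!on_grass]), 0.5)

  # hand-computed cell with several covariates
  beta <- c(intercept = -0.5, grass = 1.5, slope = -0.1, tmax_summer = -0.08)
  s2 <- true_suitability(pack, beta = beta, covariates = covs)
  lp <- -0.5 + 1.5 * covs$grass$values[10, 20] - 0.1 * covs$slope$values[10, 20] -
    0.08 * covs$tmax_summer$values[10, 20]
  expect_equal(s2$values[10, 20], plogis(lp), tolerance = 1e-12)
  expect_true(all(s2$values > 0 & s2$values < 1))
  expect_error(true_suitability(pack, beta = c(nope = 1), covariates = covs),
               "missing covariate")
})

test_that("occurrences sample proportional to suitability", {
  pack <- fixture_pack()
  s <- true_suitability(pack, covariates = fixture_covs())
  expect_equal(nrow(sample_occurrences(s, 0)), 0)

  one <- pg_raster(pack$grid, matrix(0, 60, 60))
  one$values[17, 23] <- 1
  occ <- sample_occurrences(one, 25, seed = 3)
  rc <- xy_to_rowcol(pack$grid, occ$lon, occ$lat)
  expect_true(all(rc$row == 17 & rc$col == 23))

  occ <- sample_occurrences(s, 500, seed = 4)
  expect_gt(mean(raster_at(s, occ$lon, occ$lat)), mean(s$values))

  zero <- pg_raster(pack$grid, 0)
  expect_error(sample_occurrences(zero, 5), "all zero")
})

test_that("track generator selects uniformly under beta = 0 and draws gamma lengths", {
  pack <- fixture_pack()
  covs <- fixture_covs()
  tr <- simulate_tracks(pack, 25, 200, seed = 31, beta = c(grass = 0),
                        covariates = covs, record_choice = TRUE)
  # selection index uniform over candidates (chi-square, ~5000 selections)
  idx <- attr(tr, "choice_index")
  expect_gt(length(idx), 4500)
  k_gen <- pack$truth$movement$k_gen
  p <- suppressWarnings(chisq.test(tabulate(idx, nbins = k_gen))$p.value)
  expect_gt(p, 0.01)

  # realized step lengths follow the generating gamma under beta = 0
  st <- make_steps(tr, min_points = 100)
  ks <- suppressWarnings(ks.test(st$length, "pgamma",
                                 shape = pack$truth$movement$shape,
                                 scale = pack$truth$movement$scale))
  expect_gt(ks$p.value, 0.01)

  tr2 <- simulate_tracks(pack, 2, 50, seed = 77, covariates = covs)
  tr3 <- simulate_tracks(pack, 2, 50, seed = 77, covariates = covs)
  expect_identical(tr2, tr3)
})

test_that("tracks prefer grass when selection is positive on grass", {
  pack <- fixture_pack()
  covs <- fixture_covs()
  tr <- simulate_tracks(pack, 10, 150, seed = 41, beta = c(grass = 2),
                        covariates = covs)
  avail <- mean(covs$grass$values)
  used <- mean(raster_at(covs$grass, tr$lon, tr$lat))
  expect_gt(used, avail + 0.1)
})

test_that("pseudo-future ensemble equals contemporary + delta (+ noise)", {
  truth0 <- landscape_truth(master_seed = 101L, gcm_noise_sd = 0)
  pack0 <- make_landscape(truth0, pg_grid(60, 60, 100))
  fut <- make_future(pack0, 2, seed = 5)
  expect_length(fut, 2)
  expect_equal(fut[[1]]$tmin_01$values,
               pack0$monthly_climate$tmin_01$values + truth0$future_delta[["tmin"]],
               tolerance = 1e-12)
  expect_identical(fut[[1]]$tmax_07$values, fut[[2]]$tmax_07$values)

  pack <- fixture_pack()
  fut25 <- make_future(pack, 25, seed = 6)
  expect_length(fut25, 25)   # the ensemble size used for real projections
  m <- Reduce(`+`, lapply(fut25, function(s) s$tmax_07$values)) / 25
  target <- pack$monthly_climate$tmax_07$values + pack$truth$future_delta[["tmax"]]
  tol <- 4 * pack$truth$gcm_noise_sd / sqrt(25)
  expect_lt(mean(abs(m - target)), tol)
})
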