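# step construction, movement-kernel fitting, random steps, conditional
# logistic fitting, suitability surface

make_track <- function(id, n, rate_h = 2, x = NULL, y = NULL) {
  t0 <- as.POSIXct("2021-06-01", tz = "UTC")
  data.frame(individual = id, timestamp = t0 + 3600 * rate_h * (0:(n - 1)),
             lon = x %||% cumsum(c(0, rnorm(n - 1, 0, 50))),
             lat = y %||% cumsum(c(0, rnorm(n - 1, 0, 50))))
}

test_that("make_steps filters on count and rate uniformity", {
  set.seed(1)
  short <- make_track("a", 99)
  good <- make_track("b", 120, rate_h = 4)
  st <- make_steps(rbind(short, good), min_points = 100)
  expect_equal(attr(st, "dropped"), "a")
  expect_equal(unique(st$individual), "b")
  expect_equal(nrow(st), 119)

  # irregular rates are dropped
  bad <- make_track("c", 120)
  bad$timestamp <- bad$timestamp + cumsum(runif(120, 0, 3600 * 3))
  expect_error(make_steps(bad, min_points = 100), "no individuals left")

  # three collinear equally spaced fixes: middle step turns by zero
  tri <- make_track("d", 3, x = c(0, 100, 200), y = c(0, 0, 0))
  st3 <- make_steps(tri, min_points = 3)
  expect_equal(st3$turn[2], 0)
  expect_true(is.na(st3$turn[1]))
})

test_that("movement kernels are recovered by maximum likelihood", {
  set.seed(5)
  n <- 2000
  tr <- make_track("a", n + 1)
  lens <- rgamma(n, shape = 2, scale = 100)
  turns <- runif(n, -pi, pi)                 # uniform: kappa ~ 0
  brg <- cumsum(c(0, turns[-1]))
  tr$lon <- cumsum(c(0, lens * cos(brg)))
  tr$lat <- cumsum(c(0, lens * sin(brg)))
  st <- make_steps(tr, min_points = 100)
  d <- fit_step_distributions(st)[["a"]]
  expect_gt(d$shape, 1.8); expect_lt(d$shape, 2.2)
  expect_lt(d$kappa, 0.1)

  same <- make_track("a", 50, x = seq(0, 4900, 100), y = rep(0, 50))
  stc <- make_steps(same, min_points = 10)
  expect_error(fit_step_distributions(stc, min_steps = 10), "degenerate")
})

test_that("random steps build 1 case + K controls per stratum, reproducibly", {
  set.seed(6)
  tr <- make_track("a", 11)
  st <- make_steps(tr, min_points = 5)
  expect_equal(nrow(st), 10)
  d <- list(a = list(shape = 2, scale = 100, kappa = 0.5))
  aug <- generate_random_steps(st, d, K = 15, seed = 3)
  expect_equal(nrow(aug), 160)
  expect_equal(length(unique(aug$stratum)), 10)
  expect_true(all(tapply(aug$case, aug$stratum, sum) == 1))
  expect_true(all(table(aug$stratum) == 16))
  # controls share the case start point
  expect_true(all(tapply(aug$x1, aug$stratum, function(v) diff(range(v))) == 0))

  expect_identical(generate_random_steps(st, d, K = 15, seed = 3), aug)
  expect_identical(generate_random_steps(st, d, K = 0), st)
})

test_that("conditional logistic fit matches oracles and handles degeneracy", {
  # no-information covariate: beta 0 with warning
  s <- data.frame(stratum = rep(1:3, each = 3), case = rep(c(TRUE, FALSE, FALSE), 3),
                  w = rep(5, 9), x = c(1, 0, 2, 0, 1, 2, 2, 1, 0))
  expect_warning(f0 <- fit_clogit(s, covariates = c("w", "x")), "no within-stratum")
  expect_equal(f0$beta[["w"]], 0)
  expect_true(is.na(f0$se[["w"]]))

  # mirrored strata: by symmetry beta-hat = 0
  s2 <- data.frame(stratum = rep(1:2, each = 2), case = c(TRUE, FALSE, TRUE, FALSE),
                   x = c(1, 0, 0, 1))
  f2 <- fit_clogit(s2, covariates = "x")
  expect_equal(unname(f2$beta), 0, tolerance = 1e-8)

  # partial likelihood matches an independent brute-force implementation and
  # an optimize()-refined grid oracle on a small instance
  set.seed(9)
  s3 <- data.frame(stratum = rep(1:5, each = 4),
                   case = rep(c(TRUE, FALSE, FALSE, FALSE), 5),
                   x = rnorm(20))
  f3 <- fit_clogit(s3, covariates = "x")
  brute_ll <- function(b) {
    sum(vapply(1:5, function(st) {
      rows <- s3$stratum == st
      eta <- b * s3$x[rows]
      eta[s3$case[rows]] - log(sum(exp(eta)))
    }, 0))
  }
  expect_equal(f3$logLik, brute_ll(f3$beta[["x"]]), tolerance = 1e-9)
  grid <- seq(-4, 4, by = 0.01)
  gmax <- max(vapply(grid, brute_ll, 0))
  opt <- optimize(brute_ll, c(-4, 4), maximum = TRUE)
  expect_gte(f3$logLik, gmax - 1e-6)
  expect_equal(f3$logLik, opt$objective, tolerance = 1e-8)

  # complete separation is detected
  s4 <- data.frame(stratum = rep(1:4, each = 2),
                   case = rep(c(TRUE, FALSE), 4), x = rep(c(1, 0), 4))
  expect_error(fit_clogit(s4, covariates = "x"), "separation")
})

test_that("partial likelihood is invariant to within-stratum constant shifts", {
  set.seed(10)
  s <- data.frame(stratum = rep(1:20, each = 4),
                  case = rep(c(TRUE, FALSE, FALSE, FALSE), 20), x = rnorm(80))
  f <- fit_clogit(s, covariates = "x")
  s2 <- s
  s2$x <- s$x + rep(rnorm(20, 0, 10), each = 4)   # arbitrary per-stratum offset
  f2 <- fit_clogit(s2, covariates = "x")
  expect_equal(f2$beta, f$beta, tolerance = 1e-8)
  expect_equal(f2$logLik, f$logLik, tolerance = 1e-8)
})

test_that("fit agrees with survival::clogit on simulated steps", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  pack <- fixture_pack()
  covs <- fixture_covs()
  tr <- simulate_tracks(pack, 3, 110, seed = 12, beta = c(grass = 1),
                        covariates = covs)
  st <- make_steps(tr, min_points = 100)
  d <- fit_step_distributions(st)
  aug <- generate_random_steps(st, d, K = 10, seed = 13, grid = pack$grid)
  sc <- extract_step_covariates(aug, pg_stack(list(grass = covs$grass,
                                                   elev = covs$elev)))
  mine <- fit_clogit(sc)
  ref <- survival::clogit(case ~ grass + elev + strata(stratum), data = sc)
  expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("ssf surface is the rescaled logistic of the linear predictor", {
  g <- pg_grid(4, 4, 1)
  st <- toy_stack(g, grass = matrix(seq(0, 1, length.out = 16), 4, 4),
                  elev = matrix(rnorm(16, 100, 5), 4, 4))
  f <- structure(list(beta = c(grass = 0, elev = 0), se = c(grass = NA, elev = NA),
                      covariates = c("grass", "elev"), logLik = 0, n_strata = 1),
                 class = "ssf_fit")
  flat <- ssf_surface(f, st)
  expect_true(all(flat$values == 0.5))

  f$beta <- c(grass = 2, elev = 0)
  s <- ssf_surface(f, st)
  expect_true(all(diff(as.vector(s$values)) > 0))  # monotone in grass
  expect_equal(min(s$values), 0); expect_equal(max(s$values), 1)
  # probe arithmetic: rescaled plogis(beta.x)
  p <- plogis(2 * as.vector(st$grass$values))
  expect_equal(as.vector(s$values), (p - min(p)) / diff(range(p)), tolerance = 1e-12)
})
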