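# Maxent-style model: features, penalized fitting, sweep/AIC, checkerboard,
# CV, projection, GCM ensemble, MOP

test_that("feature construction counts and scales columns as specified", {
  tab <- toy_table(50, seed = 2)
  lin <- build_features(tab, feature_spec("linear"))
  expect_equal(colnames(lin$X), "x")
  expect_true(all(lin$X >= 0 & lin$X <= 1))

  tab$b <- rep(c(0, 1), 50)
  attr(tab, "covariates") <- c("x", "b")
  lq <- build_features(tab, feature_spec(c("linear", "quadratic")))
  expect_equal(ncol(lq$X), 4)
  expect_equal(lq$X[, "b^2"], lq$X[, "b"])         # x^2 = x on {0,1}

  h <- build_features(tab[, c(names(tab)[1:5], "x")],
                      feature_spec("hinge", hinge_knots = 3))
  expect_equal(ncol(h$X), 6)                       # both orientations, 3 knots
  expect_true(all(h$penalty == 0.5))

  tab$const <- 1
  attr(tab, "covariates") <- c("x", "const")
  expect_warning(build_features(tab, feature_spec("linear")), "constant")
})

test_that("fit_maxent shrinks a null signal and recovers a real one", {
  null_tab <- toy_table(1000, seed = 5, signal = FALSE)
  m0 <- fit_maxent(null_tab, reg_multiplier = 1)
  expect_true(all(abs(m0$coefficients) < 0.05))

  sig_tab <- toy_table(500, seed = 6, signal = TRUE)
  m1 <- fit_maxent(sig_tab, reg_multiplier = 1, spec = feature_spec("linear"))
  expect_gt(m1$coefficients[["x"]], 0)

  # nonzero count never increases along the doubled-penalty path
  ks <- vapply(c(0.5, 1, 2), function(r) fit_maxent(sig_tab, r)$k, 0)
  expect_true(all(diff(ks) <= 0))

  tiny <- toy_table(5)
  expect_error(fit_maxent(tiny), ">= 10")
})

test_that("regularization sweep selects the AIC argmin over six candidates", {
  tab <- toy_table(300, seed = 7)
  sw <- sweep_regularization(tab)
  expect_equal(nrow(sw$candidates), 6)
  expect_equal(sw$candidates$reg_multiplier, seq(0.5, 3, 0.5))
  # arithmetic oracle: AIC recomputed from stored (k, logL)
  expect_equal(sw$candidates$AIC, 2 * sw$candidates$k - 2 * sw$candidates$logL)
  expect_equal(sw$candidates$AIC[sw$selected], min(sw$candidates$AIC))

  one <- sweep_regularization(tab, multipliers = 1.5)
  expect_equal(one$selected, 1)
  expect_equal(one$model$reg_multiplier, 1.5)

  # selection invariant to candidate order
  sw_rev <- sweep_regularization(tab, multipliers = rev(seq(0.5, 3, 0.5)))
  expect_equal(sw_rev$candidates$reg_multiplier[sw_rev$selected],
               sw$candidates$reg_multiplier[sw$selected])
})

test_that("checkerboard partition labels blocks by parity", {
  g <- pg_grid(4, 4, 1)
  cc <- cell_centers(g)
  folds <- checkerboard_partition(data.frame(lon = cc$x, lat = cc$y), g, 2)
  m <- matrix(folds, 4, 4)   # column-major cell order
  expect_equal(m[1:2, 1:2], matrix(1, 2, 2))
  expect_equal(m[1:2, 3:4], matrix(2, 2, 2))
  expect_equal(m[3:4, 1:2], matrix(2, 2, 2))
  expect_equal(m[3:4, 3:4], matrix(1, 2, 2))

  expect_warning(checkerboard_partition(data.frame(lon = c(.2, .3), lat = c(.2, .3)),
                                        g, 4), "single fold")

  set.seed(8)
  g2 <- pg_grid(100, 100, 1)
  pts <- data.frame(lon = runif(2000, 0, 100), lat = runif(2000, 0, 100))
  f <- checkerboard_partition(pts, g2, 10)
  expect_lt(abs(mean(f == 1) - 0.5), 0.05)
})

test_that("cross-validated AUC behaves at the extremes", {
  tab <- toy_table(200, seed = 9)
  tab$x[tab$label == "presence"] <- tab$x[tab$label == "presence"] + 2  # separable
  folds <- rep(1:2, length.out = nrow(tab))
  aucs <- cv_evaluate(tab, folds, reg_multiplier = 0.5)
  expect_length(aucs, 2)
  expect_true(all(aucs > 0.99))

  null_tab <- toy_table(400, seed = 10, signal = FALSE)
  aucs0 <- cv_evaluate(null_tab, rep(1:2, length.out = nrow(null_tab)))
  expect_lt(abs(mean(aucs0) - 0.5), 0.1)
})

test_that("surface prediction clamps, propagates nodata and matches arithmetic", {
  m <- manual_maxent("x", beta = 2, intercept = -1)
  g <- pg_grid(3, 3, 1)
  st <- toy_stack(g, x = matrix(0.5, 3, 3))
  out <- predict_surface(m, st)
  expect_equal(out$values, matrix(plogis(-1 + 2 * 0.5), 3, 3))

  vals <- matrix(seq(-0.5, 1.5, length.out = 9), 3, 3)  # out-of-range ends
  vals[2, 2] <- NA
  out2 <- predict_surface(m, toy_stack(g, x = vals))
  expect_true(is.na(out2$values[2, 2]))
  expect_gt(attr(out2, "clamp_count"), 0)
  expect_equal(out2$values[1, 1], plogis(-1 + 2 * 0))   # clamped to min
  v <- out2$values[!is.na(out2$values)]
  expect_true(all(v >= 0 & v <= 1))
  # monotone in a covariate with a single positive linear term
  expect_true(all(diff(out2$values[1, ]) >= 0))

  expect_error(predict_surface(m, toy_stack(g, y = vals)), "missing covariate")
})

test_that("GCM projection returns the stated mean and binary sum", {
  # calibrate a linear model so in-range x values map to chosen predictions
  b <- qlogis(0.9) - qlogis(0.2)
  m <- manual_maxent("x", beta = b, intercept = qlogis(0.2))
  g <- pg_grid(2, 2, 1)
  mk <- function(p) toy_stack(g, x = matrix((qlogis(p) - qlogis(0.2)) / b, 2, 2))
  stacks <- list(mk(0.2), mk(0.6), mk(0.9))
  pr <- project_gcms(m, stacks, threshold = 0.5)
  expect_equal(pr$mean_surface$values, matrix(mean(c(0.2, 0.6, 0.9)), 2, 2),
               tolerance = 1e-9)
  expect_equal(pr$binary_sum$values, matrix(2, 2, 2))

  pr_perm <- project_gcms(m, stacks[c(3, 1, 2)], threshold = 0.5)
  expect_equal(pr_perm$mean_surface$values, pr$mean_surface$values)
  expect_equal(pr_perm$binary_sum$values, pr$binary_sum$values)

  same <- project_gcms(m, list(mk(0.7), mk(0.7)), threshold = 0.5)
  expect_equal(same$mean_surface$values, matrix(0.7, 2, 2), tolerance = 1e-9)
  expect_true(all(same$binary_sum$values %in% c(0, 2)))
})

test_that("MOP matches a 1-D brute-force oracle and flags extrapolation", {
  calib_x <- c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 2.2)
  calib <- data.frame(point_id = 1:10, label = "presence", lon = 0, lat = 0,
                      month = NA, x = calib_x)
  attr(calib, "covariates") <- "x"
  g <- pg_grid(2, 2, 1)
  proj_x <- c(0.5, 2.2, 4, -1)
  st <- toy_stack(g, x = matrix(proj_x, 2, 2))

  res <- mop(calib, st, fraction = 1.0)
  # brute force: mean standardized distance to ALL calibration rows
  mu <- mean(calib_x); s <- sd(calib_x)
  brute <- vapply(proj_x, function(p) mean(abs((p - mu) / s - (calib_x - mu) / s)), 0)
  expect_equal(as.vector(res$mean_distance$values), brute, tolerance = 1e-9)
  expect_equal(as.vector(res$similarity$values), 1 - brute / max(brute),
               tolerance = 1e-9)
  expect_equal(as.vector(res$extrapolation$values), c(0, 0, 1, 1))

  # similarity is exactly 1 on a calibration point under a small fraction
  res2 <- mop(calib, toy_stack(g, x = matrix(c(0.5, 0.75, 1, 2), 2, 2)),
              fraction = 0.1)
  expect_true(all(res2$similarity$values == 1 |
                    res2$mean_distance$values > 0))
  expect_equal(res2$mean_distance$values[1, 1], 0)
  expect_equal(res2$similarity$values[1, 1], 1)

  # 1-D monotonicity: similarity non-increasing away from the cloud
  far <- seq(2.2, 6, length.out = 4)
  res3 <- mop(calib, toy_stack(g, x = matrix(far, 2, 2)), fraction = 0.3)
  sims <- as.vector(res3$similarity$values)
  expect_true(all(diff(sims) <= 1e-12))
})

test_that("maxent models survive JSON round trips", {
  tab <- toy_table(100, seed = 12)
  m <- fit_maxent(tab)
  p <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, p)
  m2 <- read_maxent(p)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$spec$normalization, m$spec$normalization, tolerance = 1e-12)
  expect_equal(predict(m2, tab), predict(m, tab), tolerance = 1e-12)
})
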