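# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# a 60x60 landscape pack with covariates, reused across test files
fixture_pack <- function() {
  if (is.null(.fixtures$pack)) {
    truth <- landscape_truth(master_seed = 101L)
    .fixtures$pack <- make_landscape(truth, pg_grid(60, 60, 100))
    .fixtures$covs <- pack_covariates(.fixtures$pack)
  }
  .fixtures$pack
}

fixture_covs <- function() {
  fixture_pack()
  .fixtures$covs
}

# presence/background sample table with a single informative covariate:
# presences sit at high x, background uniform
toy_table <- function(n = 200, seed = 1, signal = TRUE) {
  set.seed(seed)
  x_p <- if (signal) stats::rbeta(n, 4, 1.5) else stats::runif(n)
  x_b <- stats::runif(n)
  tab <- data.frame(point_id = seq_len(2 * n),
                    label = rep(c("presence", "background"), each = n),
                    lon = stats::runif(2 * n), lat = stats::runif(2 * n),
                    month = NA_integer_, x = c(x_p, x_b))
  attr(tab, "covariates") <- "x"
  tab
}

# two-covariate table for ensemble tests
toy_table2 <- function(n = 200, seed = 1, signal = TRUE) {
  set.seed(seed)
  x_p <- if (signal) stats::rbeta(n, 4, 1.5) else stats::runif(n)
  tab <- data.frame(point_id = seq_len(2 * n),
                    label = rep(c("presence", "background"), each = n),
                    lon = stats::runif(2 * n), lat = stats::runif(2 * n),
                    month = NA_integer_,
                    x = c(x_p, stats::runif(n)),
                    z = stats::rnorm(2 * n))
  attr(tab, "covariates") <- c("x", "z")
  tab
}

# toy occurrence data.frame with controllable fields
toy_occ <- function(n = 10, year = 2000, month = 6, precision = 100,
                    basis = "observation", lon = NULL, lat = NULL,
                    subspecies = "american", source = "test") {
  data.frame(lon = lon %||% stats::runif(n, 0, 10),
             lat = lat %||% stats::runif(n, 0, 10),
             year = rep_len(year, n), month = rep_len(month, n),
             precision_m = rep_len(precision, n), basis = rep_len(basis, n),
             subspecies = rep_len(subspecies, n), source = rep_len(source, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack of named constant/matrix layers on a grid
toy_stack <- function(grid, ...) {
  layers <- list(...)
  pg_stack(lapply(layers, function(v) pg_raster(grid, v)))
}

# hand-built maxent model: prediction = plogis(intercept + sum beta * x_scaled)
manual_maxent <- function(covariates, beta, intercept = 0, ranges = NULL) {
  spec <- feature_spec("linear")
  if (is.null(ranges)) ranges <- lapply(covariates, function(x) c(0, 1))
  names(ranges) <- covariates
  spec$normalization <- ranges
  structure(list(spec = spec, coefficients = stats::setNames(beta, covariates),
                 intercept = intercept, reg_multiplier = 1, lambda_base = 0.01,
                 logL = NA_real_, k = sum(beta != 0), AIC = NA_real_,
                 covariates = covariates, n_presence = NA, n_background = NA),
            class = "maxent_model")
}
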