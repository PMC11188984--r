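# Synthetic landscapes, occurrences, movement tracks and pseudo-future climate
# stacks with known ground truth. Every generator is a pure function of
# (configuration, seed), so downstream model recovery is measurable.

#' Ground-truth configuration for the synthetic landscape generator
#'
#' Bundles every knob of the stated synthetic world: Gaussian-random-field
#' parameters per layer, land-cover class prevalences, the true selection
#' coefficients, movement-kernel parameters, and the future-climate shifts.
#' Defaults describe a 10 x 10 km arid-grassland landscape at 100 m cells:
#' smooth terrain (s.d. 150 m), winter minima near -4 C and summer maxima near
#' 30 C, ~400 mm annual precipitation, cover dominated by grass/shrub, one
#' west-east major road and one minor road, gamma(2, 150 m) step lengths with
#' von Mises (kappa 0.5) turning angles, and a mid-century warming of +2.8 /
#' +3.2 C with 50 mm drying for the pseudo-GCM ensemble.
#'
#' @param master_seed Integer seed controlling every stochastic layer.
#' @param grf_params Named list of `c(mean, sill, range)` per layer
#'   (`elevation`, `tmin`, `dtr`, `precip`, `cover`, `gcm_noise`); range in m.
#' @param cover_prevalence Named numeric, class prevalences summing to 1 over
#'   `grass, shrub, barren, desert, agriculture, urban`.
#' @param beta_true Named vector of true selection coefficients over
#'   [pack_covariates()] layer names (plus `intercept`).
#' @param movement List with `shape`, `scale` (gamma step length, m), `kappa`
#'   (von Mises turning concentration), and `k_gen` (candidate count of the
#'   generative chooser, deliberately different from the analysis K = 15).
#' @param future_delta Named additive shifts for `tmin`, `tmax`, `precip`.
#' @param gcm_noise_sd Standard deviation of per-GCM smooth noise.
#' @param contemporary_truncation Quantile below which the contemporary
#'   (collapsed-range) suitability is zeroed; the historical era samples from
#'   the full surface, emulating niche reduction.
#' @return A `landscape_truth` list.
#' @export
landscape_truth <- function(master_seed = 1L,
                            grf_params = list(
                              elevation = c(mean = 800, sill = 150^2, range = 2000),
                              tmin = c(mean = -4, sill = 4, range = 3000),
                              dtr = c(mean = 14, sill = 1, range = 3000),
                              precip = c(mean = 400, sill = 100^2, range = 2500),
                              cover = c(mean = 0, sill = 1, range = 800),
                              gcm_noise = c(mean = 0, sill = 1, range = 2000)),
                            cover_prevalence = c(grass = 0.30, shrub = 0.25,
                                                 barren = 0.15, desert = 0.12,
                                                 agriculture = 0.12, urban = 0.06),
                            beta_true = c(intercept = -0.5, grass = 1.5, shrub = 0.5,
                                          slope = -0.10, tmax_summer = -0.08),
                            movement = list(shape = 2, scale = 150, kappa = 0.5,
                                            k_gen = 50),
                            future_delta = c(tmin = 2.8, tmax = 3.2, precip = -50),
                            gcm_noise_sd = 0.5,
                            contemporary_truncation = 0.6) {
  stopifnot(all(vapply(grf_params, function(p) p[["sill"]] >= 0 && p[["range"]] > 0, TRUE)),
            movement$shape > 0, movement$scale > 0, movement$kappa >= 0,
            abs(sum(cover_prevalence) - 1) < 1e-6)
  structure(list(master_seed = as.integer(master_seed), grf_params = grf_params,
                 cover_prevalence = cover_prevalence, beta_true = beta_true,
                 movement = movement, future_delta = future_delta,
                 gcm_noise_sd = gcm_noise_sd,
                 contemporary_truncation = contemporary_truncation),
            class = "landscape_truth")
}

#' Stationary Gaussian random field with exponential covariance
#'
#' Circulant-embedding (FFT) synthesis on a doubled torus; covariance
#' `sill * exp(-h / range)` with `h` the Euclidean lag in CRS units.
#' Reproducible for a fixed seed; `sill = 0` returns the constant mean.
#'
#' @param grid A `pg_grid`.
#' @param mean,sill,range Field mean, variance and correlation range (m).
#' @param seed Integer seed.
#' @return A `pg_raster`.
#' @export
gaussian_random_field <- function(grid, mean = 0, sill = 1, range = 1, seed = 1L) {
  if (range <= 0) stop("range must be positive")
  if (sill < 0) stop("sill must be >= 0")
  if (sill == 0) return(pg_raster(grid, mean))
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols; cs <- grid$cell_size
  n2 <- 2L * nr; m2 <- 2L * nc
  dr <- pmin(0:(n2 - 1), n2 - 0:(n2 - 1)) * cs
  dc <- pmin(0:(m2 - 1), m2 - 0:(m2 - 1)) * cs
  h <- sqrt(outer(dr^2, dc^2, "+"))
  C <- sill * exp(-h / range)
  lam <- Re(stats::fft(C))
  lam[lam < 0] <- 0
  eps <- matrix(stats::rnorm(n2 * m2), n2, m2) + 1i * matrix(stats::rnorm(n2 * m2), n2, m2)
  y <- stats::fft(sqrt(lam) * eps) / sqrt(as.double(n2) * m2)
  pg_raster(grid, mean + Re(y)[seq_len(nr), seq_len(nc)])
}

# connected road path across the grid as a 0/1 mask (smooth random walk)
road_path <- function(grid, seed, horizontal = TRUE) {
  set.seed(seed)
  n_main <- if (horizontal) grid$n_cols else grid$n_rows
  n_cross <- if (horizontal) grid$n_rows else grid$n_cols
  pos <- numeric(n_main)
  pos[1] <- stats::runif(1, 0.25, 0.75) * n_cross
  drift <- 0
  for (i in 2:n_main) {
    drift <- 0.8 * drift + stats::rnorm(1, 0, 0.6)
    pos[i] <- min(max(pos[i - 1] + drift, 2), n_cross - 1)
  }
  m <- matrix(0, grid$n_rows, grid$n_cols)
  idx <- pmin(pmax(round(pos), 1), n_cross)
  for (i in seq_len(n_main)) {
    if (horizontal) m[idx[i], i] <- 1 else m[i, idx[i]] <- 1
    if (i > 1) {        # fill vertical jumps so the path stays 8-connected
      lo <- min(idx[i - 1], idx[i]); hi <- max(idx[i - 1], idx[i])
      if (hi > lo + 1) {
        mid <- (lo + 1):(hi - 1)
        if (horizontal) m[mid, i] <- 1 else m[i, mid] <- 1
      }
    }
  }
  pg_raster(grid, m)
}

#' Generate a full synthetic landscape pack
#'
#' Produces aligned monthly climate (min/max temperature with a seasonal cycle,
#' coldest minima in winter and hottest maxima in summer, both lapsed with
#' elevation), annual precipitation, elevation, a categorical cover map
#' obtained by thresholding a latent field at the configured prevalence
#' quantiles, and connected major/minor road masks. Byte-identical for a fixed
#' `truth$master_seed`.
#'
#' @param truth A [landscape_truth()] configuration.
#' @param grid A `pg_grid`, at least 50 x 50.
#' @return A `landscape_pack` list with elements `monthly_climate` (pg_stack:
#'   `tmin_01..12`, `tmax_01..12`, `precip`), `elevation`, `cover_class` (codes
#'   1..6 in prevalence-vector order), `road_mask` (major road), `road_all`,
#'   `cover_codes`, `grid`, `truth`.
#' @export
make_landscape <- function(truth, grid) {
  if (grid$n_rows < 50 || grid$n_cols < 50)
    stop("grid too small (< 50x50) for track simulation")
  gp <- truth$grf_params
  sd_elev <- derive_seed(truth$master_seed, 1)
  elev <- gaussian_random_field(grid, gp$elevation[["mean"]], gp$elevation[["sill"]],
                                gp$elevation[["range"]], sd_elev)
  lapse <- (elev$values - gp$elevation[["mean"]]) * 6.5 / 1000
  tmin_base <- gaussian_random_field(grid, gp$tmin[["mean"]], gp$tmin[["sill"]],
                                     gp$tmin[["range"]], derive_seed(truth$master_seed, 2))
  dtr <- gaussian_random_field(grid, gp$dtr[["mean"]], gp$dtr[["sill"]],
                               gp$dtr[["range"]], derive_seed(truth$master_seed, 3))
  dtr$values <- pmax(dtr$values, 2)
  precip <- gaussian_random_field(grid, gp$precip[["mean"]], gp$precip[["sill"]],
                                  gp$precip[["range"]], derive_seed(truth$master_seed, 4))
  precip$values <- pmax(precip$values + 0.2 * (elev$values - gp$elevation[["mean"]]), 0)

  seasonal <- -cos(2 * pi * (1:12 - 1) / 12)       # -1 in January, +1 in July
  layers <- list()
  for (m in 1:12) {
    tm <- tmin_base$values + 9 * seasonal[m] - lapse
    layers[[sprintf("tmin_%02d", m)]] <- pg_raster(grid, tm)
    layers[[sprintf("tmax_%02d", m)]] <- pg_raster(grid, tm + dtr$values + 4 * seasonal[m])
  }
  layers[["precip"]] <- precip
  monthly_climate <- pg_stack(layers)

  latent <- gaussian_random_field(grid, 0, gp$cover[["sill"]], gp$cover[["range"]],
                                  derive_seed(truth$master_seed, 5))
  # empirical-quantile cuts of the latent field: class prevalences are exact
  # per realization while keeping the field's spatial autocorrelation
  cuts <- stats::quantile(latent$values, cumsum(truth$cover_prevalence),
                          names = FALSE, type = 1)
  codes <- matrix(findInterval(latent$values, c(-Inf, cuts[-length(cuts)]),
                               left.open = FALSE),
                  grid$n_rows, grid$n_cols)
  cover <- pg_raster(grid, codes)
  cover_codes <- stats::setNames(seq_along(truth$cover_prevalence),
                                 names(truth$cover_prevalence))

  road_major <- road_path(grid, derive_seed(truth$master_seed, 6), horizontal = TRUE)
  road_minor <- road_path(grid, derive_seed(truth$master_seed, 7), horizontal = FALSE)
  road_all <- pg_raster(grid, pmax(road_major$values, road_minor$values))

  structure(list(monthly_climate = monthly_climate, elevation = elev,
                 cover_class = cover, cover_codes = cover_codes,
                 road_mask = road_major, road_all = road_all,
                 grid = grid, truth = truth),
            class = "landscape_pack")
}

#' Predictor covariates of a landscape pack at its native grid
#'
#' The standard covariate layers the true suitability surface, the track
#' generator and every fitted model draw on: seasonal climate summaries,
#' terrain, road distance/density (radius 1 km) and per-class cover indicators
#' (0/1 at native resolution; aggregate with [cover_fractions()] for coarse
#' fraction layers).
#'
#' @param pack A `landscape_pack`.
#' @param density_radius Radius (m) for road density and TPI, default 1000.
#' @return A `pg_stack` with layers `tmin_winter`, `tmax_summer`, `precip`,
#'   `elev`, `slope`, `tpi`, `road_dist`, `road_dist_all`, `road_density`, and
#'   one indicator per cover class.
#' @export
pack_covariates <- function(pack, density_radius = 1000) {
  mc <- pack$monthly_climate
  wmon <- sprintf("tmin_%02d", c(11, 12, 1, 2))
  smon <- sprintf("tmax_%02d", 5:9)
  tmin_w <- Reduce(`+`, lapply(wmon, function(l) mc[[l]]$values)) / 4
  tmax_s <- Reduce(`+`, lapply(smon, function(l) mc[[l]]$values)) / 5
  g <- pack$grid
  layers <- list(
    tmin_winter = pg_raster(g, tmin_w),
    tmax_summer = pg_raster(g, tmax_s),
    precip = mc[["precip"]],
    elev = pack$elevation,
    slope = slope_from_elevation(pack$elevation),
    tpi = tpi(pack$elevation, max(density_radius, g$cell_size)),
    road_dist = distance_to_features(pack$road_mask),
    road_dist_all = distance_to_features(pack$road_all),
    road_density = focal_density(pack$road_all, max(density_radius, g$cell_size)))
  for (cl in names(pack$cover_codes)) {
    layers[[cl]] <- pg_raster(g, (pack$cover_class$values == pack$cover_codes[[cl]]) * 1)
  }
  pg_stack(layers)
}

#' True suitability surface of a landscape pack
#'
#' `logistic(beta0 + sum_i beta_i x_i)` over the named covariates of
#' [pack_covariates()], using raw covariate values. This is the ground truth
#' that recovery tests compare fitted models against.
#'
#' @param pack A `landscape_pack`.
#' @param beta Named coefficient vector (name `intercept` allowed); defaults to
#'   `pack$truth$beta_true`.
#' @param covariates Optional precomputed [pack_covariates()] stack.
#' @return Suitability `pg_raster` in (0, 1).
#' @export
true_suitability <- function(pack, beta = pack$truth$beta_true, covariates = NULL) {
  if (is.null(covariates)) covariates <- pack_covariates(pack)
  b0 <- if ("intercept" %in% names(beta)) beta[["intercept"]] else 0
  bnames <- setdiff(names(beta), "intercept")
  missing <- setdiff(bnames, names(covariates))
  if (length(missing)) stop("missing covariate(s): ", paste(missing, collapse = ", "))
  lp <- b0
  for (nm in bnames) lp <- lp + beta[[nm]] * covariates[[nm]]$values
  pg_raster(pack$grid, stats::plogis(lp + 0 * lp))
}

#' Contemporary (range-collapsed) suitability surface
#'
#' Zeroes the true surface below its `contemporary_truncation` quantile,
#' emulating the anthropogenic niche reduction that makes contemporary records
#' a biased sample of the full climatic niche.
#'
#' @param pack A `landscape_pack`.
#' @param covariates Optional precomputed covariate stack.
#' @return Truncated suitability `pg_raster`.
#' @export
contemporary_suitability <- function(pack, covariates = NULL) {
  s <- true_suitability(pack, covariates = covariates)
  q <- stats::quantile(s$values, pack$truth$contemporary_truncation, na.rm = TRUE, type = 1)
  v <- s$values
  v[v < q] <- 0
  pg_raster(pack$grid, v)
}

#' Sample occurrence records proportional to a suitability surface
#'
#' Cells are drawn with probability proportional to suitability, coordinates
#' jittered uniformly within the cell, and record attributes (year, month,
#' precision, basis) sampled as configured.
#'
#' @param suitability A `pg_raster` (values >= 0; NA treated as 0).
#' @param n Number of records.
#' @param attrs List of attribute samplers: `year_range` (c(min, max)),
#'   `month_probs` (length 12), `precision` (list `values` possibly containing
#'   NA, `probs`), `basis` (list `values`, `probs`), `subspecies`, `source`.
#' @param seed Integer seed.
#' @return data.frame with columns `lon, lat, year, month, precision_m, basis,
#'   subspecies, source` (an occurrence set).
#' @export
sample_occurrences <- function(suitability, n, attrs = list(), seed = 1L) {
  stopifnot(n >= 0)
  a <- utils::modifyList(list(
    year_range = c(1990, 2020), month_probs = rep(1 / 12, 12),
    precision = list(values = c(30, 100, 300, 1000, NA), probs = c(.5, .3, .12, .05, .03)),
    basis = list(values = c("observation", "specimen", "fossil"), probs = c(.95, .03, .02)),
    subspecies = "american", source = "synthetic"), attrs)
  empty <- data.frame(lon = numeric(0), lat = numeric(0), year = integer(0),
                      month = integer(0), precision_m = numeric(0),
                      basis = character(0), subspecies = character(0),
                      source = character(0))
  if (n == 0) return(empty)
  set.seed(seed)
  g <- suitability$grid
  w <- as.vector(suitability$values)
  w[is.na(w) | w < 0] <- 0
  if (sum(w) <= 0) stop("suitability is all zero; cannot sample occurrences")
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- (cells - 1L) %% g$n_rows + 1L
  col <- (cells - 1L) %/% g$n_rows + 1L
  x <- g$origin_x + (col - 1L + stats::runif(n)) * g$cell_size
  y <- g$origin_y - (row - 1L + stats::runif(n)) * g$cell_size
  data.frame(
    lon = x, lat = y,
    year = sample(seq(a$year_range[1], a$year_range[2]), n, replace = TRUE),
    month = sample(1:12, n, replace = TRUE, prob = a$month_probs),
    precision_m = sample(a$precision$values, n, replace = TRUE, prob = a$precision$probs),
    basis = sample(a$basis$values, n, replace = TRUE, prob = a$basis$probs),
    subspecies = rep(a$subspecies, n), source = rep(a$source, n))
}

#' Simulate GPS tracks by a known step-selection rule
#'
#' Each step draws `k_gen` candidate displacements (gamma lengths, von Mises
#' turns relative to the previous bearing) and selects one with probability
#' proportional to `exp(beta . x(endpoint))` — the generative twin of the SSF
#' the analysis must invert. Candidates falling off-grid are invalid; if all
#' candidates of a step are invalid the draw is retried, then the track ends
#' early (logged via attribute `truncated`).
#'
#' @param pack A `landscape_pack`.
#' @param n_individuals,n_steps Track count and steps per track (>= 1).
#' @param rate_hours Fix interval in hours.
#' @param seed Integer seed.
#' @param beta Named selection coefficients over [pack_covariates()] layers
#'   (no intercept; default `pack$truth$beta_true` minus its intercept).
#' @param covariates Optional precomputed covariate stack.
#' @return data.frame `individual, timestamp, lon, lat` (timestamp POSIXct,
#'   uniform at `rate_hours`), ordered by individual then time.
#' @export
#' @param record_choice Attach the drawn index of each selected candidate as
#'   attribute `choice_index` (selection-rank diagnostics; under `beta = 0`
#'   these indices are uniform on `1..k_gen`).
simulate_tracks <- function(pack, n_individuals, n_steps, rate_hours = 2,
                            seed = 1L, beta = NULL, covariates = NULL,
                            record_choice = FALSE) {
  stopifnot(n_individuals >= 1, n_steps >= 1)
  if (is.null(covariates)) covariates <- pack_covariates(pack)
  if (is.null(beta)) {
    beta <- pack$truth$beta_true
    beta <- beta[setdiff(names(beta), "intercept")]
  }
  missing <- setdiff(names(beta), names(covariates))
  if (length(missing)) stop("missing covariate(s): ", paste(missing, collapse = ", "))
  X <- do.call(cbind, lapply(names(beta), function(nm) as.vector(covariates[[nm]]$values)))
  eta <- as.vector(X %*% beta)
  g <- pack$grid
  mv <- pack$truth$movement
  set.seed(seed)
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  valid_cells <- which(!is.na(eta))
  out <- vector("list", n_individuals)
  truncated <- 0L
  choices <- integer(0)
  for (ind in seq_len(n_individuals)) {
    start_cell <- sample(valid_cells, 1)
    row <- (start_cell - 1L) %% g$n_rows + 1L
    col <- (start_cell - 1L) %/% g$n_rows + 1L
    x <- g$origin_x + (col - 0.5) * g$cell_size
    y <- g$origin_y - (row - 0.5) * g$cell_size
    bearing <- stats::runif(1, -pi, pi)
    xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
    xs[1] <- x; ys[1] <- y
    n_done <- 0L
    for (s in seq_len(n_steps)) {
      chosen <- NA
      for (try in 1:10) {
        len <- stats::rgamma(mv$k_gen, shape = mv$shape, scale = mv$scale)
        turn <- rvonmises(mv$k_gen, 0, mv$kappa)
        brg <- bearing + turn
        ex <- x + len * cos(brg); ey <- y + len * sin(brg)
        rc <- xy_to_rowcol(g, ex, ey)
        ok <- !is.na(rc$row)
        if (any(ok)) {
          cell <- (rc$col[ok] - 1L) * g$n_rows + rc$row[ok]
          e <- eta[cell]
          ok2 <- which(ok)[!is.na(e)]
          if (length(ok2)) {
            w <- exp(eta[(rc$col[ok2] - 1L) * g$n_rows + rc$row[ok2]])
            pick <- ok2[sample.int(length(ok2), 1, prob = w)]
            chosen <- pick
            break
          }
        }
      }
      if (is.na(chosen)) { truncated <- truncated + 1L; break }
      if (record_choice) choices <- c(choices, chosen)
      bearing <- atan2(ey[chosen] - y, ex[chosen] - x)
      x <- ex[chosen]; y <- ey[chosen]
      n_done <- s
      xs[s + 1] <- x; ys[s + 1] <- y
    }
    k <- n_done + 1L
    out[[ind]] <- data.frame(
      individual = sprintf("ind_%03d", ind),
      timestamp = t0 + 3600 * rate_hours * (0:(k - 1)),
      lon = xs[seq_len(k)], lat = ys[seq_len(k)])
  }
  res <- do.call(rbind, out)
  attr(res, "truncated") <- truncated
  if (record_choice) attr(res, "choice_index") <- choices
  res
}

#' Build a pseudo-future climate ensemble
#'
#' Each pseudo-GCM stack equals the contemporary monthly climate plus the
#' configured additive shift per variable plus one spatially smooth noise field
#' per GCM and variable group (sd `gcm_noise_sd`), shared coherently across the
#' months of that group.
#'
#' @param pack A `landscape_pack`.
#' @param n_gcm Number of pseudo-GCMs (>= 1).
#' @param seed Integer seed.
#' @return List of `pg_stack`s, names `gcm_01`, ...
#' @export
make_future <- function(pack, n_gcm, seed = 1L) {
  stopifnot(n_gcm >= 1)
  truth <- pack$truth
  delta <- truth$future_delta
  gp <- truth$grf_params$gcm_noise
  out <- vector("list", n_gcm)
  for (gcm in seq_len(n_gcm)) {
    noise <- list()
    for (grp in c("tmin", "tmax", "precip")) {
      noise[[grp]] <- if (truth$gcm_noise_sd > 0)
        gaussian_random_field(pack$grid, 0, truth$gcm_noise_sd^2, gp[["range"]],
                              derive_seed(seed, gcm * 17 + match(grp, c("tmin", "tmax", "precip"))))$values
      else matrix(0, pack$grid$n_rows, pack$grid$n_cols)
    }
    layers <- lapply(names(pack$monthly_climate), function(nm) {
      grp <- if (startsWith(nm, "tmin")) "tmin" else if (startsWith(nm, "tmax")) "tmax" else "precip"
      v <- pack$monthly_climate[[nm]]$values + delta[[grp]] + noise[[grp]]
      if (grp == "precip") v <- pmax(v, 0)
      pg_raster(pack$grid, v)
    })
    names(layers) <- names(pack$monthly_climate)
    out[[gcm]] <- pg_stack(layers)
  }
  names(out) <- sprintf("gcm_%02d", seq_len(n_gcm))
  out
}
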