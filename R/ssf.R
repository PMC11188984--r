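# Step-selection function: step construction from GPS tracks, per-individual
# movement-kernel fitting (gamma step lengths, von Mises turns), random-step
# generation (1 case + K controls per stratum), stratified conditional
# logistic regression by Newton iteration on the partial likelihood, and a
# suitability surface from the habitat coefficients.

# hours between consecutive timestamps (POSIXct or numeric hours)
.dt_hours <- function(ts) {
  if (inherits(ts, "POSIXct")) as.numeric(diff(ts), units = "hours") else diff(as.numeric(ts))
}

#' Build case steps from GPS tracks
#'
#' Individuals with fewer than `min_points` fixes or without a uniform sample
#' rate (median absolute deviation of fix intervals above
#' `rate_tolerance * rate`, rates matched to the nearest allowed value) are
#' dropped and logged. Gaps longer than the tolerated interval split a track
#' into bursts rather than producing phantom steps; the first step of a burst
#' has no previous bearing (`prev_bearing = NA`).
#'
#' @param tracks data.frame `individual, timestamp, lon, lat`, time-ordered
#'   within individual.
#' @param min_points Minimum fixes per individual (default 100).
#' @param allowed_rates_h Permitted fix rates in hours.
#' @param rate_tolerance Relative tolerance on fix intervals (default 0.1).
#' @return A `step_set` data.frame: `individual, stratum, x1, y1, x2, y2,
#'   t_start, length, bearing, prev_bearing, turn, case`, with attribute
#'   `dropped` naming the filtered individuals.
#' @export
make_steps <- function(tracks, min_points = 100, allowed_rates_h = c(1, 2, 4, 13),
                       rate_tolerance = 0.1) {
  stopifnot(all(c("individual", "timestamp", "lon", "lat") %in% names(tracks)))
  out <- list(); dropped <- character(0)
  for (id in unique(tracks$individual)) {
    tr <- tracks[tracks$individual == id, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    if (nrow(tr) < min_points) { dropped <- c(dropped, id); next }
    dt <- .dt_hours(tr$timestamp)
    rate <- allowed_rates_h[which.min(abs(allowed_rates_h - stats::median(dt)))]
    if (stats::median(abs(dt - rate)) > rate_tolerance * rate) {
      dropped <- c(dropped, id); next
    }
    ok_step <- abs(dt - rate) <= rate_tolerance * rate
    n <- nrow(tr)
    dx <- diff(tr$lon); dy <- diff(tr$lat)
    len <- sqrt(dx^2 + dy^2)
    brg <- atan2(dy, dx)
    step_rows <- which(ok_step)
    if (length(step_rows) == 0) { dropped <- c(dropped, id); next }
    prev <- rep(NA_real_, n - 1)
    for (i in step_rows) {
      if (i > 1 && ok_step[i - 1]) prev[i] <- brg[i - 1]
    }
    out[[id]] <- data.frame(
      individual = id,
      stratum = paste0(id, "_", step_rows),
      x1 = tr$lon[step_rows], y1 = tr$lat[step_rows],
      x2 = tr$lon[step_rows + 1], y2 = tr$lat[step_rows + 1],
      t_start = tr$timestamp[step_rows],
      length = len[step_rows], bearing = brg[step_rows],
      prev_bearing = prev[step_rows],
      turn = wrap_angle(brg[step_rows] - prev[step_rows]),
      case = TRUE)
  }
  if (length(out) == 0) stop("no individuals left after filtering")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  class(res) <- c("step_set", "data.frame")
  res
}

#' Fit per-individual step-length and turning-angle distributions
#'
#' Gamma by maximum likelihood on observed case-step lengths; von Mises
#' concentration on observed turning angles (mean direction fixed at 0).
#'
#' @param steps A `step_set` (case steps are used).
#' @param min_steps Minimum case steps per individual (default 30).
#' @return Named list per individual: `shape`, `scale`, `kappa`, `n`.
#' @export
fit_step_distributions <- function(steps, min_steps = 30) {
  out <- list()
  for (id in unique(steps$individual)) {
    s <- steps[steps$individual == id & steps$case, , drop = FALSE]
    if (nrow(s) < min_steps) stop("individual ", id, " has < ", min_steps, " case steps")
    len <- pmax(s$length, 1e-6)
    gm <- gamma_mle(len)
    turns <- s$turn[!is.na(s$turn)]
    kappa <- if (length(turns) >= 5) vonmises_mle(turns)$kappa else 0
    out[[id]] <- list(shape = gm$shape, scale = gm$scale, kappa = kappa, n = nrow(s))
  }
  out
}

#' Generate K random control steps per observed step
#'
#' Controls share the case's start point; lengths are drawn from the
#' individual's fitted gamma and turns from its fitted von Mises relative to
#' the previous bearing (uniform bearing when the case has none). With a grid
#' supplied, off-grid control endpoints are redrawn up to `max_retry` times,
#' then dropped with a log.
#'
#' @param steps A `step_set` of case steps.
#' @param dists Output of [fit_step_distributions()].
#' @param K Controls per case (default 15).
#' @param seed Integer seed.
#' @param grid Optional `pg_grid` used to reject off-grid endpoints.
#' @param max_retry Redraw attempts per off-grid control.
#' @return Augmented `step_set` (cases followed by controls), attribute
#'   `dropped_controls` counting undrawable controls.
#' @export
generate_random_steps <- function(steps, dists, K = 15, seed = 1L, grid = NULL,
                                  max_retry = 10) {
  if (K == 0) return(steps)
  miss <- setdiff(unique(steps$individual), names(dists))
  if (length(miss)) stop("no step distributions for: ", paste(miss, collapse = ", "))
  set.seed(seed)
  cases <- steps[steps$case, , drop = FALSE]
  n <- nrow(cases)
  dropped <- 0L
  ctl <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- cases[i, ]
    d <- dists[[cs$individual]]
    base_bearing <- if (is.na(cs$prev_bearing)) stats::runif(1, -pi, pi) else cs$prev_bearing
    len <- stats::rgamma(K, shape = d$shape, scale = d$scale)
    turn <- rvonmises(K, 0, d$kappa)
    brg <- base_bearing + turn
    x2 <- cs$x1 + len * cos(brg); y2 <- cs$y1 + len * sin(brg)
    if (!is.null(grid)) {
      for (r in seq_len(max_retry)) {
        bad <- is.na(xy_to_rowcol(grid, x2, y2)$row)
        if (!any(bad)) break
        nb <- sum(bad)
        len[bad] <- stats::rgamma(nb, shape = d$shape, scale = d$scale)
        turn[bad] <- rvonmises(nb, 0, d$kappa)
        brg <- base_bearing + turn
        x2[bad] <- cs$x1 + len[bad] * cos(brg[bad])
        y2[bad] <- cs$y1 + len[bad] * sin(brg[bad])
      }
      bad <- is.na(xy_to_rowcol(grid, x2, y2)$row)
      dropped <- dropped + sum(bad)
      keep <- !bad
    } else keep <- rep(TRUE, K)
    if (!any(keep)) { ctl[i] <- list(NULL); next }
    ctl[[i]] <- data.frame(
      individual = cs$individual, stratum = cs$stratum,
      x1 = cs$x1, y1 = cs$y1, x2 = x2[keep], y2 = y2[keep],
      t_start = cs$t_start, length = len[keep],
      bearing = wrap_angle(brg[keep]), prev_bearing = base_bearing,
      turn = turn[keep], case = FALSE)
  }
  res <- rbind(cases, do.call(rbind, ctl))
  res <- res[order(res$stratum, -res$case), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_controls") <- dropped
  class(res) <- c("step_set", "data.frame")
  res
}

#' Attach step-endpoint covariates from a raster stack
#'
#' Reads every stack layer at each step endpoint. Rows hitting nodata or
#' falling off-grid are removed; strata left without their case or without any
#' control are removed entirely (counts in attribute `drop_log`).
#'
#' @param steps A `step_set`.
#' @param stack A `pg_stack`.
#' @param layers Layer names to extract (default all).
#' @return `step_set` with one covariate column per layer.
#' @export
extract_step_covariates <- function(steps, stack, layers = names(stack)) {
  vals <- lapply(layers, function(nm) raster_at(stack[[nm]], steps$x2, steps$y2))
  names(vals) <- layers
  out <- cbind(as.data.frame(steps), as.data.frame(vals))
  ok <- stats::complete.cases(out[, layers, drop = FALSE])
  out <- out[ok, , drop = FALSE]
  tab_case <- tapply(out$case, out$stratum, sum)
  tab_n <- tapply(rep(1, nrow(out)), out$stratum, sum)
  good <- names(tab_case)[tab_case == 1 & tab_n >= 2]
  res <- out[out$stratum %in% good, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "drop_log") <- c(rows_nodata = sum(!ok),
                             strata_dropped = length(tab_case) - length(good))
  attr(res, "covariates") <- layers
  class(res) <- c("step_set", "data.frame")
  res
}

# stratified conditional logistic partial log-likelihood, gradient, Hessian
clogit_ll <- function(beta, X, case, sidx, n_strata) {
  eta <- as.vector(X %*% beta)
  m <- as.vector(tapply(eta, sidx, max)[as.character(seq_len(n_strata))])
  e <- as.vector(exp(eta - m[sidx]))
  denom <- as.vector(rowsum(e, sidx))
  ll <- sum(eta[case]) - sum(m + log(denom))
  p <- as.vector(e / denom[sidx])
  grad <- colSums(X[case, , drop = FALSE]) - colSums(X * p)
  mu <- rowsum(X * p, sidx)
  H <- crossprod(X * sqrt(p)) - crossprod(mu)   # observed information
  list(ll = ll, grad = grad, H = H)
}

#' Fit a step-selection function by conditional logistic regression
#'
#' Maximizes the stratified partial likelihood
#' `sum_s log( exp(b'x_case) / sum_j exp(b'x_j) )` by Newton iterations with
#' step halving; standard errors from the inverse observed information.
#' Covariates without within-stratum variation carry no information: their
#' coefficient is reported as 0 with `NA` standard error, with a warning.
#' Complete separation (unbounded likelihood) raises an explicit error.
#'
#' @param steps A `step_set` with covariate columns (>= 2 strata, exactly one
#'   case per stratum).
#' @param covariates Covariate column names (default: extracted layers).
#' @param max_iter,tol Newton controls.
#' @return An `ssf_fit`: `beta`, `se`, `vcov`, `logLik`, `n_strata`,
#'   `covariates`.
#' @export
fit_clogit <- function(steps, covariates = attr(steps, "covariates"),
                       max_iter = 50, tol = 1e-10) {
  if (is.null(covariates)) stop("covariates must be given")
  strata <- factor(steps$stratum)
  n_strata <- nlevels(strata)
  if (n_strata < 2) stop("need >= 2 strata")
  if (!all(tapply(steps$case, strata, sum) == 1))
    stop("each stratum must contain exactly one case")
  sidx <- as.integer(strata)
  X0 <- as.matrix(steps[, covariates, drop = FALSE])
  # center within stratum (invariance of the partial likelihood) for stability
  Xc <- X0 - rowsum(X0, sidx)[sidx, , drop = FALSE] /
    as.vector(table(sidx))[sidx]
  wvar <- apply(Xc, 2, function(v) max(abs(v)))
  keep <- wvar > 1e-10
  if (any(!keep))
    warning("no within-stratum variation; coefficient set to 0 for: ",
            paste(covariates[!keep], collapse = ", "))
  if (!any(keep)) {
    beta_full <- stats::setNames(rep(0, length(covariates)), covariates)
    se_full <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
    ll0 <- -sum(log(as.vector(table(sidx))))
    return(structure(list(beta = beta_full, se = se_full, vcov = NULL,
                          logLik = ll0, n_strata = n_strata,
                          covariates = covariates), class = "ssf_fit"))
  }
  X <- Xc[, keep, drop = FALSE]
  case <- steps$case
  beta <- rep(0, ncol(X))
  cur <- clogit_ll(beta, X, case, sidx, n_strata)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$H, cur$grad), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix")
    ok <- FALSE
    for (half in 0:30) {
      beta_new <- beta + step / 2^half
      nxt <- clogit_ll(beta_new, X, case, sidx, n_strata)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) stop("step-halving failed: likely complete separation")
    delta <- nxt$ll - cur$ll
    beta <- beta_new; cur <- nxt
    if (delta < tol && sqrt(sum(cur$grad^2)) < 1e-6) { converged <- TRUE; break }
  }
  # at complete separation the partial likelihood approaches its supremum 0
  if (!converged || cur$ll > -1e-6 * n_strata)
    stop("complete separation: partial likelihood unbounded at its supremum")
  V <- solve(cur$H)
  beta_full <- stats::setNames(rep(0, length(covariates)), covariates)
  se_full <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
  beta_full[covariates[keep]] <- beta
  se_full[covariates[keep]] <- sqrt(diag(V))
  structure(list(beta = beta_full, se = se_full, vcov = V, logLik = cur$ll,
                 n_strata = n_strata, covariates = covariates),
            class = "ssf_fit")
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("<ssf_fit: %d strata, logLik %.3f>\n", x$n_strata, x$logLik))
  print(data.frame(beta = x$beta, se = x$se))
  invisible(x)
}

#' Habitat suitability surface from fitted SSF coefficients
#'
#' `logistic(beta' x)` per cell, min-max rescaled to `[0, 1]` over valid
#' cells; any monotone transform yields identical percentile-threshold
#' binaries downstream.
#'
#' @param fit An `ssf_fit`.
#' @param stack A `pg_stack` with all fitted covariates.
#' @return Suitability `pg_raster`.
#' @export
ssf_surface <- function(fit, stack) {
  miss <- setdiff(fit$covariates, names(stack))
  if (length(miss)) stop("stack missing covariate layer(s): ",
                         paste(miss, collapse = ", "))
  lp <- 0
  for (nm in fit$covariates) lp <- lp + fit$beta[[nm]] * stack[[nm]]$values
  if (length(lp) == 1) lp <- matrix(lp, stack_grid(stack)$n_rows, stack_grid(stack)$n_cols)
  p <- stats::plogis(lp)
  rng <- range(p, na.rm = TRUE)
  v <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0 + 0.5
  pg_raster(stack_grid(stack), v)
}

#' Read / write track CSV files (`individual,timestamp,lon,lat`)
#' @param path CSV path.
#' @return data.frame of tracks with POSIXct timestamps.
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("track CSV missing columns: ", paste(miss, collapse = ", "))
  tr$timestamp <- as.POSIXct(tr$timestamp, tz = "UTC")
  tr
}

#' @rdname read_tracks
#' @param tracks data.frame of tracks.
#' @export
write_tracks <- function(tracks, path) {
  tr <- tracks
  tr$timestamp <- format(tr$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
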