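# Maxent-style presence/background climate model: lasso-penalized logistic
# regression on linear/quadratic/hinge features of min-max scaled covariates
# (the maxnet parameterization), with a regularization-multiplier sweep and
# AIC selection, spatial checkerboard partitioning, projection with clamping,
# and the mobility-oriented parity (MOP) extrapolation screen.

#' Feature specification for Maxent-style fitting
#'
#' @param classes Subset of `c("linear", "quadratic", "hinge")`.
#' @param hinge_knots Number of interior knots per covariate when hinge
#'   features are enabled (each knot yields a forward and a reverse hinge).
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(classes = c("linear", "quadratic"), hinge_knots = 3) {
  classes <- match.arg(classes, c("linear", "quadratic", "hinge"), several.ok = TRUE)
  if (length(classes) == 0) stop("at least one feature class required")
  structure(list(classes = classes, hinge_knots = hinge_knots,
                 normalization = NULL), class = "feature_spec")
}

# scale covariate matrix to [0,1] by stored (min, max); returns matrix
scale_covariates <- function(M, norm, clamp = FALSE) {
  out <- M
  n_clamped <- 0L
  for (j in colnames(M)) {
    r <- norm[[j]]
    v <- M[, j]
    if (clamp) {
      n_clamped <- n_clamped + sum(v < r[1] | v > r[2], na.rm = TRUE)
      v <- pmin(pmax(v, r[1]), r[2])
    }
    out[, j] <- (v - r[1]) / (r[2] - r[1])
  }
  attr(out, "n_clamped") <- n_clamped
  out
}

# expand scaled covariates into feature columns; returns list(X, penalty)
expand_features <- function(S, spec) {
  cols <- list(); pen <- numeric(0)
  for (j in colnames(S)) {
    x <- S[, j]
    if ("linear" %in% spec$classes) {
      cols[[j]] <- x; pen <- c(pen, 1)
    }
    if ("quadratic" %in% spec$classes) {
      cols[[paste0(j, "^2")]] <- x^2; pen <- c(pen, 1)
    }
    if ("hinge" %in% spec$classes && spec$hinge_knots > 0) {
      knots <- seq_len(spec$hinge_knots) / (spec$hinge_knots + 1)
      for (t in knots) {
        cols[[sprintf("hinge(%s>%.3f)", j, t)]] <- pmax(0, (x - t) / (1 - t))
        cols[[sprintf("hinge(%s<%.3f)", j, t)]] <- pmax(0, (t - x) / t)
        pen <- c(pen, 0.5, 0.5)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, penalty = pen)
}

#' Build the Maxent design matrix from a sample table
#'
#' Covariates are min-max scaled to `[0, 1]` on the presence + background
#' range, then expanded per feature class. Constant covariates are dropped
#' with a warning. The returned spec stores the normalization so prediction
#' uses the training ranges.
#'
#' @param table Sample table from [extract_covariates()].
#' @param spec A [feature_spec()].
#' @return List with `X` (design matrix), `y` (1 = presence), `spec` (with
#'   normalization filled), `penalty` (per-column penalty factors).
#' @export
build_features <- function(table, spec = feature_spec()) {
  covs <- sample_covariates(table)
  M <- as.matrix(table[, covs, drop = FALSE])
  keep <- apply(M, 2, function(v) diff(range(v, na.rm = TRUE)) > 0)
  if (any(!keep)) {
    warning("constant covariate(s) dropped: ", paste(covs[!keep], collapse = ", "))
    M <- M[, keep, drop = FALSE]
  }
  if (ncol(M) == 0) stop("no non-constant covariates")
  norm <- lapply(as.data.frame(M), range)
  spec$normalization <- norm
  S <- scale_covariates(M, norm)
  ef <- expand_features(S, spec)
  list(X = ef$X, y = as.integer(table$label == "presence"), spec = spec,
       penalty = ef$penalty)
}

#' Fit a Maxent-style penalized presence/background model
#'
#' Lasso-penalized logistic regression of presence (1) against background (0)
#' on the expanded feature matrix, penalty `reg_multiplier * lambda_base`
#' scaled per feature class (hinge features carry half weight, as in maxnet
#' defaults). Output is on the logistic `[0, 1]` scale; since downstream
#' thresholds are occurrence-percentile based, any monotone transform yields
#' identical binary maps.
#'
#' @param table Sample table (>= 10 presences and >= 10 background rows).
#' @param reg_multiplier Positive regularization multiplier.
#' @param spec A [feature_spec()].
#' @param lambda_base Base penalty at multiplier 1 (default 0.01).
#' @return A `maxent_model` with coefficients, training ranges, unpenalized
#'   log-likelihood `logL`, nonzero-coefficient count `k` and `AIC = 2k - 2 logL`.
#' @export
fit_maxent <- function(table, reg_multiplier = 1, spec = feature_spec(),
                       lambda_base = 0.01) {
  stopifnot(reg_multiplier > 0)
  y <- as.integer(table$label == "presence")
  if (sum(y == 1) < 10 || sum(y == 0) < 10)
    stop("need >= 10 presences and >= 10 background points")
  bf <- build_features(table, spec)
  if (ncol(bf$X) == 1L) {   # glmnet needs >= 2 columns; pad with an inert zero
    bf$X <- cbind(bf$X, `.dummy` = 0)
    bf$penalty <- c(bf$penalty, 1)
  }
  lam <- reg_multiplier * lambda_base
  fit <- glmnet::glmnet(bf$X, bf$y, family = "binomial", alpha = 1,
                        lambda = lam * c(16, 8, 4, 2, 1),
                        penalty.factor = bf$penalty, standardize = FALSE,
                        maxit = 2e5)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- rownames(fit$beta)
  beta <- beta[names(beta) != ".dummy"]
  a0 <- fit$a0[length(fit$a0)]
  eta <- as.vector(bf$X[, names(beta), drop = FALSE] %*% beta) + a0
  p <- stats::plogis(eta)
  logL <- sum(bf$y * log(pmax(p, 1e-12)) + (1 - bf$y) * log(pmax(1 - p, 1e-12)))
  k <- sum(beta != 0)
  structure(list(spec = bf$spec, coefficients = beta, intercept = unname(a0),
                 reg_multiplier = reg_multiplier, lambda_base = lambda_base,
                 logL = logL, k = k, AIC = 2 * k - 2 * logL,
                 covariates = names(bf$spec$normalization),
                 n_presence = sum(y == 1), n_background = sum(y == 0)),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model: %d covariates, reg %.2f, k = %d nonzero, AIC = %.2f>\n",
              length(x$covariates), x$reg_multiplier, x$k, x$AIC))
  invisible(x)
}

# predict from a covariate matrix (columns = model covariates), with clamping
predict_maxent_matrix <- function(model, M) {
  S <- scale_covariates(M, model$spec$normalization, clamp = TRUE)
  X <- expand_features(S, model$spec)$X
  p <- stats::plogis(as.vector(X %*% model$coefficients) + model$intercept)
  attr(p, "n_clamped") <- attr(S, "n_clamped")
  p
}

#' Predict a maxent model on new rows of a sample table
#' @param object A `maxent_model`.
#' @param newdata Sample table or data.frame containing the model covariates.
#' @param ... Unused.
#' @return Numeric predictions in `[0, 1]`.
#' @export
predict.maxent_model <- function(object, newdata, ...) {
  M <- as.matrix(newdata[, object$covariates, drop = FALSE])
  as.numeric(predict_maxent_matrix(object, M))
}

#' Sweep the regularization multiplier and select the lowest-AIC model
#'
#' One candidate per multiplier; `AIC = 2k - 2 logL` with `k` the count of
#' nonzero penalized coefficients; selection is the AIC argmin, ties resolved
#' toward the larger (more parsimonious) multiplier. Selection is invariant to
#' candidate order.
#'
#' @param table Sample table.
#' @param multipliers Positive multipliers (default 0.5 to 3.0 by 0.5).
#' @param spec A [feature_spec()].
#' @param lambda_base Base penalty.
#' @return A `sweep_result`: list with `candidates` (data.frame reg, logL, k,
#'   AIC), `models` (list), `selected` (index), `model` (selected model).
#' @export
sweep_regularization <- function(table, multipliers = seq(0.5, 3, by = 0.5),
                                 spec = feature_spec(), lambda_base = 0.01) {
  if (length(multipliers) == 0) stop("multipliers must be nonempty")
  models <- list(); ok <- logical(length(multipliers))
  for (i in seq_along(multipliers)) {
    models[[i]] <- tryCatch(fit_maxent(table, multipliers[i], spec, lambda_base),
                            error = function(e) e)
    ok[i] <- inherits(models[[i]], "maxent_model")
  }
  if (!any(ok)) stop("all fits failed")
  cand <- data.frame(reg_multiplier = multipliers,
                     logL = vapply(models, function(m) if (inherits(m, "maxent_model")) m$logL else NA_real_, 0),
                     k = vapply(models, function(m) if (inherits(m, "maxent_model")) m$k else NA_real_, 0))
  cand$AIC <- 2 * cand$k - 2 * cand$logL
  aic <- ifelse(ok, cand$AIC, Inf)
  best <- which(aic == min(aic))
  selected <- best[which.max(multipliers[best])]
  structure(list(candidates = cand, models = models, selected = selected,
                 model = models[[selected]]), class = "sweep_result")
}

#' Checkerboard spatial partition into two folds
#'
#' Aggregates the template grid into `aggregation_factor` x
#' `aggregation_factor` blocks and labels each point by the parity of its
#' block (fold 1 or 2).
#'
#' @param points data.frame with lon/lat inside the template.
#' @param template A `pg_grid`.
#' @param aggregation_factor Block size in cells (>= 1).
#' @return Integer fold labels (1/2), one per point.
#' @export
checkerboard_partition <- function(points, template, aggregation_factor = 1) {
  stopifnot(aggregation_factor >= 1)
  rc <- xy_to_rowcol(template, points$lon, points$lat)
  if (any(is.na(rc$row))) stop("point outside grid")
  br <- (rc$row - 1L) %/% aggregation_factor
  bc <- (rc$col - 1L) %/% aggregation_factor
  fold <- as.integer((br + bc) %% 2L) + 1L
  if (length(unique(fold)) == 1L) warning("all points fall in a single fold")
  fold
}

#' Cross-validated AUC per fold
#'
#' Fits on all but one fold and scores held-out presences against held-out
#' background with AUC, for each occupied fold. Folds lacking either class
#' are skipped with a message.
#'
#' @param table Sample table.
#' @param folds Integer fold labels, one per row of `table`.
#' @param reg_multiplier Regularization multiplier for the refits.
#' @param spec A [feature_spec()].
#' @return Named numeric vector of per-fold AUCs.
#' @export
cv_evaluate <- function(table, folds, reg_multiplier = 1, spec = feature_spec()) {
  stopifnot(nrow(table) == length(folds))
  ids <- sort(unique(folds))
  if (length(ids) < 2) stop("need >= 2 occupied folds")
  out <- numeric(0)
  for (f in ids) {
    test <- table[folds == f, , drop = FALSE]
    train <- table[folds != f, , drop = FALSE]
    if (!all(c("presence", "background") %in% test$label)) {
      message("fold ", f, " lacks a class; skipped")
      next
    }
    attr(train, "covariates") <- sample_covariates(table)
    m <- fit_maxent(train, reg_multiplier, spec)
    p <- predict(m, test)
    out[as.character(f)] <- rank_auc(p[test$label == "presence"],
                                     p[test$label == "background"])
  }
  out
}

#' Project a fitted model onto a raster stack
#'
#' Covariates are clamped to the training range before the feature transform
#' (the number of clamped values is reported in the `clamp_count` attribute);
#' nodata propagates.
#'
#' @param model A `maxent_model`.
#' @param stack A `pg_stack` containing every model covariate as a layer.
#' @return Prediction `pg_raster` in `[0, 1]` with attribute `clamp_count`.
#' @export
predict_surface <- function(model, stack) {
  miss <- setdiff(model$covariates, names(stack))
  if (length(miss)) stop("stack missing covariate layer(s): ",
                         paste(miss, collapse = ", "))
  M <- do.call(cbind, lapply(model$covariates, function(nm) as.vector(stack[[nm]]$values)))
  colnames(M) <- model$covariates
  p <- predict_maxent_matrix(model, M)
  out <- raster_from_vector(stack_grid(stack), as.numeric(p))
  attr(out, "clamp_count") <- attr(p, "n_clamped")
  out
}

#' Project onto a future-climate ensemble: mean surface and binary sum
#'
#' Predicts the model on each future stack, returning the cellwise mean
#' suitability and the count of stacks whose prediction meets the threshold.
#'
#' @param model A `maxent_model`.
#' @param future_stacks List of `pg_stack`s on one common grid.
#' @param threshold Suitability threshold in `[0, 1]`.
#' @return List with `mean_surface` (pg_raster) and `binary_sum` (pg_raster
#'   with values 0..n_gcm).
#' @export
project_gcms <- function(model, future_stacks, threshold) {
  stopifnot(length(future_stacks) >= 1, threshold >= 0, threshold <= 1)
  g <- stack_grid(future_stacks[[1]])
  for (s in future_stacks) if (!grids_aligned(g, stack_grid(s)))
    stop("future stacks on inconsistent grids")
  acc <- 0; cnt <- 0
  for (s in future_stacks) {
    p <- predict_surface(model, s)$values
    acc <- acc + p
    cnt <- cnt + (p >= threshold)
  }
  list(mean_surface = pg_raster(g, acc / length(future_stacks)),
       binary_sum = pg_raster(g, cnt))
}

#' Mobility-oriented parity (MOP) extrapolation screen
#'
#' For every projection cell, the mean Euclidean distance (covariates
#' standardized by the calibration mean/sd) to the nearest
#' `ceil(fraction * n)` calibration rows (subsampled to `sample_rows`),
#' rescaled to similarity `1 - d / d_max` in `[0, 1]`. Cells with any raw
#' covariate outside the calibration min-max range are flagged extrapolative.
#'
#' @param calibration_table Sample table (>= 10 rows).
#' @param projection_stack `pg_stack` with the calibration covariates.
#' @param fraction Fraction of the calibration cloud to average over (0, 1].
#' @param sample_rows Maximum calibration rows used (subsampled).
#' @param seed Seed for the subsample.
#' @return A `mop_surface`: list with `similarity` (pg_raster),
#'   `extrapolation` (0/1 pg_raster), `mean_distance` (pg_raster).
#' @export
mop <- function(calibration_table, projection_stack, fraction = 0.10,
                sample_rows = 2000, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  covs <- intersect(sample_covariates(calibration_table), names(projection_stack))
  if (length(covs) == 0) stop("projection stack shares no covariates with calibration")
  C <- as.matrix(calibration_table[, covs, drop = FALSE])
  if (nrow(C) < 10) stop("need >= 10 calibration rows")
  if (nrow(C) > sample_rows) {
    set.seed(seed)
    C <- C[sample.int(nrow(C), sample_rows), , drop = FALSE]
  }
  mu <- colMeans(C); sd <- apply(C, 2, stats::sd)
  sd[sd == 0] <- 1
  Cs <- sweep(sweep(C, 2, mu), 2, sd, "/")
  P <- do.call(cbind, lapply(covs, function(nm) as.vector(projection_stack[[nm]]$values)))
  colnames(P) <- covs
  valid <- stats::complete.cases(P)
  k <- max(1L, ceiling(fraction * nrow(Cs)))
  d <- rep(NA_real_, nrow(P))
  if (any(valid)) {
    Ps <- sweep(sweep(P[valid, , drop = FALSE], 2, mu), 2, sd, "/")
    nn <- FNN::get.knnx(Cs, Ps, k = k)$nn.dist
    d[valid] <- rowMeans(nn)
  }
  d_max <- max(d, na.rm = TRUE)
  sim <- if (d_max > 0) 1 - d / d_max else ifelse(is.na(d), NA_real_, 1)
  lo <- apply(C, 2, min); hi <- apply(C, 2, max)
  extr <- rep(NA_real_, nrow(P))
  extr[valid] <- apply(P[valid, , drop = FALSE], 1, function(r) any(r < lo | r > hi)) * 1
  g <- stack_grid(projection_stack)
  structure(list(similarity = raster_from_vector(g, sim),
                 extrapolation = raster_from_vector(g, extr),
                 mean_distance = raster_from_vector(g, d)),
            class = "mop_surface")
}

#' Serialize / restore a maxent model as versioned JSON text
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @return `path` (write) or the restored `maxent_model` (read).
#' @export
write_maxent <- function(model, path) {
  obj <- list(format = "prongscape-maxent-1",
              classes = model$spec$classes, hinge_knots = model$spec$hinge_knots,
              normalization = model$spec$normalization,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept, reg_multiplier = model$reg_multiplier,
              lambda_base = model$lambda_base, logL = model$logL, k = model$k,
              AIC = model$AIC, covariates = model$covariates,
              n_presence = model$n_presence, n_background = model$n_background)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "prongscape-maxent-1")) stop("unknown model format")
  spec <- feature_spec(obj$classes, obj$hinge_knots)
  spec$normalization <- lapply(obj$normalization, as.numeric)
  structure(list(spec = spec, coefficients = unlist(obj$coefficients),
                 intercept = obj$intercept, reg_multiplier = obj$reg_multiplier,
                 lambda_base = obj$lambda_base, logL = obj$logL, k = obj$k,
                 AIC = obj$AIC, covariates = obj$covariates,
                 n_presence = obj$n_presence, n_background = obj$n_background),
            class = "maxent_model")
}
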