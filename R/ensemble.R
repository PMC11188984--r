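# Four-learner ensemble resource selection function: Maxent-style penalized
# logistic, random forest, CART, and a plain GLM with logistic link, fitted on
# identical presence/background rows and combined by an unweighted mean.

#' Fit the four-member ensemble habitat model
#'
#' Every member is fitted on the same rows; a non-convergent member raises an
#' error rather than being dropped silently. The default predictor set is
#' whatever covariates the sample table carries (the reduced road/land-cover
#' set in the standard pipeline).
#'
#' @param table Sample table with both labels and >= 30 rows.
#' @param config List: `n_trees` (forest size, default 500), `seed`,
#'   `reg_multiplier` (maxent member), `max_depth`, `min_leaf`.
#' @return An `ensemble_model`.
#' @export
fit_ensemble <- function(table, config = list()) {
  cfg <- utils::modifyList(list(n_trees = 500, seed = 1L, reg_multiplier = 1,
                                max_depth = 12, min_leaf = 5), config)
  if (nrow(table) < 30) stop("need >= 30 rows")
  y <- as.integer(table$label == "presence")
  if (length(unique(y)) < 2) stop("single-class input")
  covs <- sample_covariates(table)
  X <- as.matrix(table[, covs, drop = FALSE])

  members <- list()
  members$maxent <- fit_maxent(table, cfg$reg_multiplier)
  members$random_forest <- rf_fit(X, y, n_trees = cfg$n_trees,
                                  min_leaf = cfg$min_leaf,
                                  max_depth = cfg$max_depth, seed = cfg$seed)
  members$cart <- cart_fit(X, y, min_leaf = cfg$min_leaf, max_depth = cfg$max_depth)
  # perfect separation makes glm.fit warn and report converged = FALSE while
  # still yielding a perfectly ranking fit; only undefined coefficients are a
  # genuine member failure
  glm_fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                             family = stats::binomial()))
  if (anyNA(glm_fit$coefficients)) stop("glm member failed (NA coefficients)")
  members$glm_logistic <- stats::setNames(glm_fit$coefficients,
                                          c("(Intercept)", covs))
  structure(list(members = members, covariates = covs, config = cfg,
                 source = attr(table, "source")), class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model: %d members on %d covariates>\n",
              length(x$members), length(x$covariates)))
  invisible(x)
}

# per-member predictions from a raw covariate matrix; NA rows propagate
ensemble_member_matrix <- function(model, M) {
  ok <- stats::complete.cases(M)
  pred1 <- function(f) {
    out <- rep(NA_real_, nrow(M))
    if (any(ok)) out[ok] <- f(M[ok, , drop = FALSE])
    out
  }
  b <- model$members$glm_logistic
  cbind(
    maxent = pred1(function(m) predict_maxent_matrix(model$members$maxent, m)),
    random_forest = pred1(function(m) predict(model$members$random_forest, m)),
    cart = pred1(function(m) predict(model$members$cart, m)),
    glm_logistic = pred1(function(m) stats::plogis(as.vector(cbind(1, m) %*% b))))
}

#' Predict the ensemble on new sample-table rows
#' @param object An `ensemble_model`.
#' @param newdata data.frame with the model covariates.
#' @param members Return the per-member matrix instead of the mean.
#' @param ... Unused.
#' @return Mean prediction vector, or the member matrix.
#' @export
predict.ensemble_model <- function(object, newdata, members = FALSE, ...) {
  M <- as.matrix(newdata[, object$covariates, drop = FALSE])
  P <- ensemble_member_matrix(object, M)
  if (members) P else rowMeans(P)
}

#' Predict the ensemble onto a raster stack
#'
#' Cellwise unweighted mean of the four member predictions; nodata propagates.
#'
#' @param model An `ensemble_model`.
#' @param stack A `pg_stack` with every training covariate.
#' @return Prediction `pg_raster` in `[0, 1]`.
#' @export
predict_ensemble <- function(model, stack) {
  miss <- setdiff(model$covariates, names(stack))
  if (length(miss)) stop("stack missing covariate layer(s): ",
                         paste(miss, collapse = ", "))
  M <- do.call(cbind, lapply(model$covariates, function(nm) as.vector(stack[[nm]]$values)))
  colnames(M) <- model$covariates
  raster_from_vector(stack_grid(stack), rowMeans(ensemble_member_matrix(model, M)))
}
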