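# Expert-driven habitat suitability index: piecewise-linear response curves
# for road distance and slope, multiplied with the summed fraction of four
# open-cover classes, with urban/agriculture conflict cells zeroed.

#' Piecewise-linear response curve on [0, 1]
#'
#' Linear interpolation between breakpoints, clamped to the end values outside
#' the breakpoint range.
#'
#' @param breakpoints Strictly ascending predictor values.
#' @param values Suitability at the breakpoints, each in `[0, 1]`.
#' @return A `response_curve` function-like object; evaluate with
#'   [eval_curve()].
#' @export
response_curve <- function(breakpoints, values) {
  stopifnot(length(breakpoints) == length(values), length(breakpoints) >= 2)
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly ascending")
  if (any(values < 0 | values > 1)) stop("curve values outside [0,1]")
  structure(list(breakpoints = as.numeric(breakpoints), values = as.numeric(values)),
            class = "response_curve")
}

#' Evaluate a response curve
#' @param curve A [response_curve()].
#' @param x Predictor values.
#' @return Suitability in `[0, 1]`; NA propagates.
#' @export
eval_curve <- function(curve, x) {
  stats::approx(curve$breakpoints, curve$values, xout = x, rule = 2)$y
}

#' Packaged default expert model
#'
#' Default curves are declared configuration values, not literature facts:
#' road suitability rises linearly from 0 at the road to 1 at `road_full_m`
#' (1 km), slope suitability is 1 on flat ground up to `slope_flat_deg` (10
#' degrees) and declines linearly to 0 at `slope_zero_deg` (30 degrees). All
#' pieces are overridable.
#'
#' @param road_curve,slope_curve Optional [response_curve()] overrides.
#' @param road_full_m,slope_flat_deg,slope_zero_deg Default-curve knots.
#' @param sum_classes Cover classes whose fractions are summed.
#' @param zero_classes Conflict classes that zero suitability.
#' @param zero_threshold Combined conflict fraction above which a cell is
#'   zeroed (majority rule, 0.5).
#' @return An `expert_model` list.
#' @export
default_curves <- function(road_curve = NULL, slope_curve = NULL,
                           road_full_m = 1000, slope_flat_deg = 10,
                           slope_zero_deg = 30,
                           sum_classes = c("barren", "desert", "grass", "shrub"),
                           zero_classes = c("urban", "agriculture"),
                           zero_threshold = 0.5) {
  if (is.null(road_curve)) road_curve <- response_curve(c(0, road_full_m), c(0, 1))
  if (is.null(slope_curve))
    slope_curve <- response_curve(c(0, slope_flat_deg, slope_zero_deg), c(1, 1, 0))
  structure(list(road_curve = road_curve, slope_curve = slope_curve,
                 sum_classes = sum_classes, zero_classes = zero_classes,
                 zero_threshold = zero_threshold), class = "expert_model")
}

#' Expert habitat suitability surface
#'
#' `S = road_curve(distance) * slope_curve(slope) * (f_barren + f_desert +
#' f_grass + f_shrub)`, then cells whose combined urban + agriculture fraction
#' exceeds the zeroing threshold are set to 0. Cover layers are named
#' `frac_<class>` or `<class>`.
#'
#' @param stack `pg_stack` providing `road_dist`, `slope` and the six cover
#'   fraction layers.
#' @param model An [default_curves()] expert model.
#' @return Suitability `pg_raster` in `[0, 1]`.
#' @export
expert_suitability <- function(stack, model = default_curves()) {
  layer <- function(nm) {
    if (nm %in% names(stack)) return(stack[[nm]]$values)
    alt <- paste0("frac_", nm)
    if (alt %in% names(stack)) return(stack[[alt]]$values)
    stop("stack missing layer: ", nm)
  }
  road <- layer("road_dist"); slope <- layer("slope")
  covsum <- Reduce(`+`, lapply(model$sum_classes, layer))
  allsum <- covsum + Reduce(`+`, lapply(model$zero_classes, layer))
  if (any(allsum > 1 + 1e-6, na.rm = TRUE))
    stop("cover fractions sum above 1")
  S <- eval_curve(model$road_curve, road) * eval_curve(model$slope_curve, slope) * covsum
  conflict <- Reduce(`+`, lapply(model$zero_classes, layer))
  S[!is.na(conflict) & conflict > model$zero_threshold] <- 0
  g <- stack_grid(stack)
  pg_raster(g, matrix(S, g$n_rows, g$n_cols))
}

#' Serialize / restore an expert model as JSON text
#' @param model An `expert_model`.
#' @param path File path.
#' @return `path`, or the restored model.
#' @export
write_expert <- function(model, path) {
  obj <- list(format = "prongscape-expert-1",
              road_curve = model$road_curve[c("breakpoints", "values")],
              slope_curve = model$slope_curve[c("breakpoints", "values")],
              sum_classes = model$sum_classes, zero_classes = model$zero_classes,
              zero_threshold = model$zero_threshold)
  writeLines(jsonlite::toJSON(obj, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_expert
#' @export
read_expert <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "prongscape-expert-1")) stop("unknown model format")
  default_curves(
    road_curve = response_curve(obj$road_curve$breakpoints, obj$road_curve$values),
    slope_curve = response_curve(obj$slope_curve$breakpoints, obj$slope_curve$values),
    sum_classes = obj$sum_classes, zero_classes = obj$zero_classes,
    zero_threshold = obj$zero_threshold)
}
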