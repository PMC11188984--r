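# Model evaluation: Mann-Whitney AUC and the continuous Boyce index, plus the
# cross-evaluation pairing rule (a model is scored on data from a source
# other than its own training source).

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a random presence score outranks a random background
#' score, ties counted half.
#'
#' @param presence_scores,background_scores Nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0)
    stop("score vectors must be nonempty")
  rank_auc(presence_scores, background_scores)
}

#' Continuous Boyce index
#'
#' Overlapping moving windows across the score range; for each window,
#' P = fraction of presence scores inside it, E = fraction of valid map cells
#' inside it, and the index is the Spearman rank correlation between window
#' midpoint and P/E over windows with E > 0 (average ranks on ties). A
#' constant surface has no rankable windows and returns a flagged NA.
#'
#' @param surface Suitability `pg_raster`.
#' @param presence_points data.frame with lon/lat (>= 20 on valid cells).
#' @param n_windows Number of windows (default 101).
#' @param window_width Width as a fraction of the score range (default 0.1).
#' @return List: `boyce` (number or NA), `flag` (`"ok"`/`"constant_surface"`),
#'   `bin_table` (midpoint, P, E, PE).
#' @export
boyce <- function(surface, presence_points, n_windows = 101, window_width = 0.1) {
  vals <- as.vector(surface$values)
  vals <- vals[!is.na(vals)]
  pres <- raster_at(surface, presence_points$lon, presence_points$lat)
  pres <- pres[!is.na(pres)]
  if (length(pres) < 20) stop("need >= 20 presence points on valid cells")
  rng <- range(vals)
  if (diff(rng) == 0)
    return(list(boyce = NA_real_, flag = "constant_surface", bin_table = NULL))
  w <- window_width * diff(rng)
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  P <- vapply(mids, function(m) mean(pres >= m - w / 2 & pres <= m + w / 2), 0)
  E <- vapply(mids, function(m) mean(vals >= m - w / 2 & vals <= m + w / 2), 0)
  keep <- E > 0
  pe <- P[keep] / E[keep]
  mids_k <- mids[keep]
  # drop consecutive duplicate P/E values (overlapping windows replicate the
  # same presence set; the standard continuous-index implementations dedup
  # before correlating so a monotone placement scores exactly 1)
  first <- c(TRUE, diff(pe) != 0)
  b <- suppressWarnings(stats::cor(mids_k[first], pe[first], method = "spearman"))
  list(boyce = b, flag = "ok",
       bin_table = data.frame(midpoint = mids_k, P = P[keep], E = E[keep],
                              PE = pe))
}

#' Cross-evaluate models against independent datasets
#'
#' Scores each (model surface, evaluation dataset) pair with AUC (presence vs
#' background drawn uniformly from valid cells) and the Boyce index. A model
#' is refused on a dataset carrying its own training source tag unless
#' `allow_self = TRUE`.
#'
#' @param surfaces Named list of suitability `pg_raster`s.
#' @param sources Named character: training source tag per surface.
#' @param datasets Named list of data.frames (lon/lat), each with a
#'   `source` attribute or entry in `dataset_sources`.
#' @param dataset_sources Named character: source tag per dataset.
#' @param pairing data.frame with columns `model`, `dataset` naming the pairs
#'   to evaluate.
#' @param n_background Background sample size for AUC (default 1000).
#' @param seed Integer seed.
#' @param allow_self Permit evaluating a model on its own training source.
#' @return data.frame report: model, dataset, model_source, dataset_source,
#'   auc, boyce, n_presence, n_background.
#' @export
cross_evaluate <- function(surfaces, sources, datasets, dataset_sources,
                           pairing, n_background = 1000, seed = 1L,
                           allow_self = FALSE) {
  out <- list()
  for (i in seq_len(nrow(pairing))) {
    mn <- pairing$model[i]; dn <- pairing$dataset[i]
    ms <- sources[[mn]]; ds <- dataset_sources[[dn]]
    if (identical(ms, ds) && !allow_self)
      stop("refusing to evaluate model '", mn, "' on its own training source '",
           ms, "' (use allow_self)")
    surf <- surfaces[[mn]]
    pts <- datasets[[dn]]
    pres <- raster_at(surf, pts$lon, pts$lat)
    pres <- pres[!is.na(pres)]
    vals <- as.vector(surf$values)
    vals <- vals[!is.na(vals)]
    set.seed(derive_seed(seed, i))
    bg <- sample(vals, min(n_background, length(vals)), replace = TRUE)
    b <- boyce(surf, pts)
    out[[i]] <- data.frame(model = mn, dataset = dn, model_source = ms,
                           dataset_source = ds, auc = auc(pres, bg),
                           boyce = b$boyce, n_presence = length(pres),
                           n_background = length(bg))
  }
  do.call(rbind, out)
}
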