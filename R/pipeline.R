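# End-to-end orchestration: synthetic landscape -> occurrence conditioning ->
# dual-hypothesis climate models -> future ensemble + MOP -> three habitat
# models -> percentile thresholds -> climate clip -> 0-3 consensus -> conflict
# mask -> areas -> cross-evaluation. Every stage is seeded from the master
# seed and logs its parameters, so a rerun is bit-identical.

#' Default pipeline configuration
#'
#' Every key used anywhere in the pipeline, with the stated-world defaults:
#' a 100 x 100 grid of 100 m cells, 1500 contemporary and 200 historical
#' occurrence records, 8 collared individuals at 150 steps each (2 h fixes),
#' K = 15 random steps, regularization sweep 0.5-3.0 by 0.5, HSS/LSS retained
#' fractions 0.85/0.95, habitat threshold 0.99, 3 pseudo-GCMs, MOP fraction
#' 0.10 with 2000 rows, and a 200-tree forest (desk-scale; see vignette).
#'
#' @param seed Master seed.
#' @param out_dir Artifact directory.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 7L, out_dir = tempfile("prongscape_run_")) {
  list(
    seed = as.integer(seed), out_dir = out_dir, simulate = TRUE,
    grid = list(n_rows = 100, n_cols = 100, cell_size = 100),
    n_occurrences = 1500, n_historical = 200, n_supplement_pool = 60,
    supplement_n = 20, era_cutoff = 1950,
    min_year = 1980, max_precision_m = 500, lon_max = NULL,
    n_individuals = 8, n_steps = 150, rate_hours = 2,
    k_random = 15, ssf_min_points = 100,
    reg_grid = seq(0.5, 3, by = 0.5), features = c("linear", "quadratic"),
    buffer_km = 25, checkerboard_factor = 10,
    hss_retained = 0.85, lss_retained = 0.95, habitat_retained = 0.99,
    n_gcm = 3, mop_fraction = 0.10, mop_rows = 2000,
    rf_trees = 200, conflict_threshold = 0.5,
    density_radius = 1000,
    rsf_covariates = c("road_dist", "road_density", "agriculture", "barren",
                       "grass", "shrub", "urban"),
    ssf_covariates = c("road_dist", "road_dist_all", "road_density", "elev",
                       "slope", "tpi", "agriculture", "barren", "grass",
                       "shrub", "urban"),
    write_geotiffs = TRUE)
}

# seasonal climate summaries used for model projection
summarize_climate <- function(monthly, slope) {
  g <- stack_grid(monthly)
  wmon <- sprintf("tmin_%02d", c(11, 12, 1, 2))
  smon <- sprintf("tmax_%02d", 5:9)
  pg_stack(list(
    tmin = pg_raster(g, Reduce(`+`, lapply(wmon, function(l) monthly[[l]]$values)) / 4),
    tmax = pg_raster(g, Reduce(`+`, lapply(smon, function(l) monthly[[l]]$values)) / 5),
    precip = monthly[["precip"]], slope = slope))
}

.log_line <- function(log_path, stage, ...) {
  msg <- paste0("[", stage, "] ", paste(..., collapse = " "))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  invisible(msg)
}

#' Run the full multiscale pipeline
#'
#' Executes, in order: landscape simulation, occurrence filtering and seasonal
#' splitting, the two seasonal migration-hypothesis climate models and the
#' niche-reduction climate model (each a regularization sweep with AIC
#' selection), projection onto the pseudo-GCM ensemble with MOP screening,
#' the three habitat models (ensemble RSF, SSF, expert HSI), occurrence-
#' percentile thresholding, climate clipping, consensus summation (current and
#' future), conflict masking, area accounting and cross-evaluation. Artifacts
#' (GeoTIFF rasters, CSV tables, JSON models, a structured log) are written
#' under `config$out_dir`.
#'
#' @param config List from [default_config()] (possibly modified) or a path to
#'   a JSON config file.
#' @param stop_after Optional stage name to stop at: one of `"simulate"`,
#'   `"prep"`, `"fit_climate"`, `"project"`, `"mop"`, `"fit_rsf"`, `"fit_ssf"`,
#'   `"expert"`, `"evaluate"`, `"consensus"`.
#' @return Invisible list of all stage results (see names).
#' @export
run_pipeline <- function(config = default_config(), stop_after = NULL) {
  if (is.character(config)) {
    config <- utils::modifyList(default_config(), jsonlite::fromJSON(config))
  }
  cfg <- utils::modifyList(default_config(seed = config$seed %||% 7L), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  cat("", file = log_path)
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(cfg$out_dir, "config_echo.json"))
  res <- list(config = cfg)
  done <- function(stage) !is.null(stop_after) && identical(stage, stop_after)
  save_tif <- function(r, name) {
    if (cfg$write_geotiffs) write_geotiff(r, file.path(cfg$out_dir, paste0(name, ".tif")))
  }

  ## -- simulate ------------------------------------------------------------
  grid <- pg_grid(cfg$grid$n_rows, cfg$grid$n_cols, cfg$grid$cell_size)
  truth <- landscape_truth(master_seed = cfg$seed)
  pack <- make_landscape(truth, grid)
  covs <- pack_covariates(pack, density_radius = cfg$density_radius)
  suit_true <- true_suitability(pack, covariates = covs)
  suit_cont <- contemporary_suitability(pack, covariates = covs)
  occ_cont <- sample_occurrences(suit_cont, cfg$n_occurrences,
                                 seed = derive_seed(cfg$seed, 101))
  occ_hist <- sample_occurrences(
    suit_true, cfg$n_historical,
    attrs = list(year_range = c(1880, cfg$era_cutoff),
                 precision = list(values = c(100, 500, 2000), probs = c(.5, .3, .2))),
    seed = derive_seed(cfg$seed, 102))
  occ_supp <- sample_occurrences(
    suit_true, cfg$n_supplement_pool,
    attrs = list(year_range = c(1960, 2000), subspecies = "sonoran"),
    seed = derive_seed(cfg$seed, 103))
  occ_all <- rbind(occ_cont, occ_hist, occ_supp)
  tracks <- simulate_tracks(pack, cfg$n_individuals, cfg$n_steps,
                            rate_hours = cfg$rate_hours,
                            seed = derive_seed(cfg$seed, 104), covariates = covs)
  write_occurrences(occ_all, file.path(cfg$out_dir, "occurrences.csv"))
  write_tracks(tracks, file.path(cfg$out_dir, "tracks.csv"))
  save_tif(suit_true, "true_suitability")
  .log_line(log_path, "simulate", "seed", cfg$seed, "grid",
            paste0(grid$n_rows, "x", grid$n_cols), "occ", nrow(occ_all),
            "track_pts", nrow(tracks))
  res$pack <- pack; res$covariates <- covs; res$occurrences <- occ_all
  res$tracks <- tracks; res$true_suitability <- suit_true
  if (done("simulate")) return(invisible(res))

  ## -- prep ----------------------------------------------------------------
  occ_f <- filter_records(occ_cont, min_year = cfg$min_year,
                          max_precision_m = cfg$max_precision_m,
                          lon_max = cfg$lon_max)
  seasons <- split_seasons(occ_f)
  occ_niche <- historical_set(occ_all, era_cutoff = cfg$era_cutoff,
                              supplement_tag = "sonoran",
                              n_supplement = cfg$supplement_n,
                              seed = derive_seed(cfg$seed, 105))
  .log_line(log_path, "prep", "filtered", nrow(occ_f), "winter",
            nrow(seasons$winter), "summer", nrow(seasons$summer),
            "niche", nrow(occ_niche))
  res$seasons <- seasons; res$occ_niche <- occ_niche
  if (done("prep")) return(invisible(res))

  ## -- fit_climate ---------------------------------------------------------
  monthly <- pack$monthly_climate
  season_model <- function(occ_season, monthly_var, extra_layers, season_months, tag) {
    thin <- thin_to_cell(occ_season, grid)
    bg <- sample_background(thin, grid, buffer_km = cfg$buffer_km,
                            seed = derive_seed(cfg$seed, 110 + nchar(tag)))
    set.seed(derive_seed(cfg$seed, 120 + nchar(tag)))
    bg$month <- sample(season_months, nrow(bg), replace = TRUE)
    ext_layers <- c(monthly[grep(paste0("^", monthly_var, "_"), names(monthly))],
                    extra_layers)
    ext <- pg_stack(ext_layers)
    tab_p <- extract_covariates(thin, ext, label = "presence",
                                month_matched = TRUE, monthly_vars = monthly_var)
    tab_b <- extract_covariates(bg, ext, label = "background",
                                month_matched = TRUE, monthly_vars = monthly_var)
    tab <- rbind(tab_p, tab_b)
    attr(tab, "covariates") <- attr(tab_p, "covariates")
    sw <- sweep_regularization(tab, multipliers = cfg$reg_grid,
                               spec = feature_spec(cfg$features))
    list(table = tab, sweep = sw, model = sw$model, thin = thin)
  }
  winter <- season_model(seasons$winter, "tmin", list(slope = covs$slope),
                         c(11, 12, 1, 2), "winter")
  summer <- season_model(seasons$summer, "tmax",
                         list(precip = monthly$precip, slope = covs$slope),
                         5:9, "summerX")
  # niche-reduction model: historical records, climate-summary covariates
  clim_sum <- summarize_climate(monthly, covs$slope)
  clim_sum_stack <- clim_sum
  niche_thin <- thin_to_cell(occ_niche, grid)
  niche_bg <- sample_background(niche_thin, grid, buffer_km = cfg$buffer_km,
                                seed = derive_seed(cfg$seed, 130))
  tab_np <- extract_covariates(niche_thin, clim_sum_stack, label = "presence")
  tab_nb <- extract_covariates(niche_bg, clim_sum_stack, label = "background")
  niche_tab <- rbind(tab_np, tab_nb)
  attr(niche_tab, "covariates") <- attr(tab_np, "covariates")
  niche_sw <- sweep_regularization(niche_tab, multipliers = cfg$reg_grid,
                                   spec = feature_spec(cfg$features))
  niche_model <- niche_sw$model
  for (nm in c("winter", "summer", "niche")) {
    sw <- switch(nm, winter = winter$sweep, summer = summer$sweep, niche = niche_sw)
    utils::write.csv(sw$candidates,
                     file.path(cfg$out_dir, paste0("sweep_", nm, ".csv")),
                     row.names = FALSE)
    .log_line(log_path, "fit_climate", nm, "selected reg",
              sw$candidates$reg_multiplier[sw$selected], "AIC",
              round(sw$candidates$AIC[sw$selected], 2))
  }
  write_maxent(niche_model, file.path(cfg$out_dir, "model_niche.json"))
  # spatial (checkerboard) cross-validated AUC at the selected multiplier
  cv <- list()
  for (nm in c("winter", "summer", "niche")) {
    sw <- switch(nm, winter = winter$sweep, summer = summer$sweep, niche = niche_sw)
    tab <- switch(nm, winter = winter$table, summer = summer$table, niche = niche_tab)
    folds <- checkerboard_partition(tab, grid, cfg$checkerboard_factor)
    cv[[nm]] <- tryCatch(
      cv_evaluate(tab, folds, sw$candidates$reg_multiplier[sw$selected],
                  spec = feature_spec(cfg$features)),
      error = function(e) { .log_line(log_path, "fit_climate", nm, "cv failed:",
                                      conditionMessage(e)); NULL })
    if (!is.null(cv[[nm]]))
      .log_line(log_path, "fit_climate", nm, "cv_auc",
                paste(round(cv[[nm]], 3), collapse = "/"))
  }
  res$cv <- cv
  res$winter <- winter; res$summer <- summer
  res$niche <- list(table = niche_tab, sweep = niche_sw, model = niche_model,
                    thin = niche_thin)
  if (done("fit_climate")) return(invisible(res))

  ## -- project + mop -------------------------------------------------------
  niche_surface <- predict_surface(niche_model, clim_sum_stack)
  niche_lss <- threshold_at_occurrences(niche_surface, niche_thin, cfg$lss_retained)
  niche_hss <- threshold_at_occurrences(niche_surface, niche_thin, cfg$hss_retained)
  winter_stack <- pg_stack(list(tmin = clim_sum$tmin, slope = covs$slope))
  summer_stack <- pg_stack(list(tmax = clim_sum$tmax, precip = monthly$precip,
                                slope = covs$slope))
  winter_surface <- predict_surface(winter$model, winter_stack)
  summer_surface <- predict_surface(summer$model, summer_stack)
  winter_bin <- threshold_at_occurrences(winter_surface, winter$thin, cfg$hss_retained)
  summer_bin <- threshold_at_occurrences(summer_surface, summer$thin, cfg$hss_retained)
  migration_bin <- clip_to_climate(winter_bin$binary, summer_bin$binary)  # AND

  future <- make_future(pack, cfg$n_gcm, seed = derive_seed(cfg$seed, 140))
  future_sum <- lapply(future, summarize_climate, slope = covs$slope)
  proj <- project_gcms(niche_model, future_sum, threshold = niche_lss$threshold)
  future_bin <- pg_raster(grid, (proj$mean_surface$values >= niche_lss$threshold) * 1)
  class(future_bin) <- c("binary_map", class(future_bin))
  save_tif(niche_surface, "climate_niche_surface")
  save_tif(proj$mean_surface, "climate_future_mean")
  save_tif(proj$binary_sum, "climate_future_gcm_count")
  .log_line(log_path, "project", "n_gcm", cfg$n_gcm, "lss_threshold",
            signif(niche_lss$threshold, 6))
  res$climate <- list(niche_surface = niche_surface, niche_lss = niche_lss,
                      niche_hss = niche_hss, winter_surface = winter_surface,
                      summer_surface = summer_surface,
                      migration_binary = migration_bin,
                      future = proj, future_binary = future_bin)
  if (done("project")) return(invisible(res))

  mop_res <- mop(res$niche$table, future_sum[[1]], fraction = cfg$mop_fraction,
                 sample_rows = cfg$mop_rows, seed = derive_seed(cfg$seed, 141))
  save_tif(mop_res$similarity, "mop_similarity")
  .log_line(log_path, "mop", "fraction", cfg$mop_fraction, "rows", cfg$mop_rows)
  res$mop <- mop_res
  if (done("mop")) return(invisible(res))

  ## -- habitat models ------------------------------------------------------
  habitat_stack <- covs
  track_pts <- data.frame(lon = tracks$lon, lat = tracks$lat)
  rsf_thin <- thin_to_cell(track_pts, grid)
  rsf_bg <- sample_background(rsf_thin, grid, buffer_km = cfg$buffer_km,
                              seed = derive_seed(cfg$seed, 150))
  rsf_stack <- pg_stack(stats::setNames(
    lapply(cfg$rsf_covariates, function(nm) habitat_stack[[nm]]), cfg$rsf_covariates))
  tab_rp <- extract_covariates(rsf_thin, rsf_stack, label = "presence")
  tab_rb <- extract_covariates(rsf_bg, rsf_stack, label = "background")
  rsf_tab <- rbind(tab_rp, tab_rb)
  attr(rsf_tab, "covariates") <- attr(tab_rp, "covariates")
  attr(rsf_tab, "source") <- "collar"
  ens <- fit_ensemble(rsf_tab, config = list(n_trees = cfg$rf_trees,
                                             seed = derive_seed(cfg$seed, 151)))
  rsf_surface <- predict_ensemble(ens, rsf_stack)
  save_tif(rsf_surface, "habitat_rsf")
  .log_line(log_path, "fit_rsf", "rows", nrow(rsf_tab), "trees", cfg$rf_trees)
  res$rsf <- list(table = rsf_tab, model = ens, surface = rsf_surface)
  if (done("fit_rsf")) return(invisible(res))

  steps <- make_steps(tracks, min_points = cfg$ssf_min_points,
                      rate_tolerance = 0.1)
  dists <- fit_step_distributions(steps)
  stepset <- generate_random_steps(steps, dists, K = cfg$k_random,
                                   seed = derive_seed(cfg$seed, 152), grid = grid)
  ssf_stack <- pg_stack(stats::setNames(
    lapply(cfg$ssf_covariates, function(nm) habitat_stack[[nm]]), cfg$ssf_covariates))
  stepcov <- extract_step_covariates(stepset, ssf_stack)
  ssf_fit <- fit_clogit(stepcov)
  ssf_surf <- ssf_surface(ssf_fit, ssf_stack)
  utils::write.csv(data.frame(covariate = names(ssf_fit$beta), beta = ssf_fit$beta,
                              se = ssf_fit$se),
                   file.path(cfg$out_dir, "ssf_coefficients.csv"), row.names = FALSE)
  save_tif(ssf_surf, "habitat_ssf")
  .log_line(log_path, "fit_ssf", "strata", ssf_fit$n_strata, "K", cfg$k_random)
  res$ssf <- list(steps = stepcov, fit = ssf_fit, surface = ssf_surf)
  if (done("fit_ssf")) return(invisible(res))

  expert_model <- default_curves(zero_threshold = cfg$conflict_threshold)
  expert_surf <- expert_suitability(habitat_stack, expert_model)
  save_tif(expert_surf, "habitat_expert")
  .log_line(log_path, "expert", "classes", paste(expert_model$sum_classes, collapse = "+"))
  res$expert <- list(model = expert_model, surface = expert_surf)
  if (done("expert")) return(invisible(res))

  ## -- evaluate ------------------------------------------------------------
  eval_report <- cross_evaluate(
    surfaces = list(rsf = rsf_surface, ssf = ssf_surf, expert = expert_surf),
    sources = c(rsf = "collar", ssf = "collar", expert = "expert"),
    datasets = list(observations = occ_f, collar_points = track_pts),
    dataset_sources = c(observations = "observation", collar_points = "collar"),
    pairing = data.frame(model = c("rsf", "ssf", "expert"),
                         dataset = c("observations", "observations", "collar_points")),
    seed = derive_seed(cfg$seed, 160))
  utils::write.csv(eval_report, file.path(cfg$out_dir, "evaluation.csv"),
                   row.names = FALSE)
  .log_line(log_path, "evaluate", "rows", nrow(eval_report))
  res$evaluation <- eval_report
  if (done("evaluate")) return(invisible(res))

  ## -- consensus -----------------------------------------------------------
  occ_pts <- occ_f
  habitat_bins <- lapply(list(rsf = rsf_surface, ssf = ssf_surf,
                              expert = expert_surf),
                         function(s) threshold_at_occurrences(s, occ_pts,
                                                              cfg$habitat_retained)$binary)
  clip_now <- lapply(habitat_bins, clip_to_climate, climate = niche_lss$binary)
  clip_fut <- lapply(habitat_bins, clip_to_climate, climate = future_bin)
  conflict_frac <- habitat_stack$urban$values + habitat_stack$agriculture$values
  conflict <- pg_raster(grid, (conflict_frac > cfg$conflict_threshold) * 1)
  cons_now <- mask_conflict(consensus_sum(clip_now), conflict)
  cons_fut <- mask_conflict(consensus_sum(clip_fut), conflict)
  areas_now <- area_by_class(cons_now)
  areas_fut <- area_by_class(cons_fut)
  save_tif(cons_now, "consensus_current")
  save_tif(cons_fut, "consensus_future")
  utils::write.csv(cbind(period = "current", areas_now),
                   file.path(cfg$out_dir, "areas_current.csv"), row.names = FALSE)
  utils::write.csv(cbind(period = "future", areas_fut),
                   file.path(cfg$out_dir, "areas_future.csv"), row.names = FALSE)
  .log_line(log_path, "consensus", "classes_now",
            paste(areas_now$class, collapse = ","), "classes_fut",
            paste(areas_fut$class, collapse = ","))
  res$consensus <- list(current = cons_now, future = cons_fut,
                        areas_current = areas_now, areas_future = areas_fut,
                        conflict = conflict, binaries = habitat_bins)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate`, `prep`, `fit-climate`, `project`, `mop`,
#' `fit-rsf`, `fit-ssf`, `expert`, `evaluate`, `consensus`, `run`. All run the
#' pipeline from a config (`--config file.json`, `--seed N`, `--out dir`,
#' `--grid NxM`, `--simulate`) and stop after the named stage (`run` executes
#' everything).
#'
#' @param args Character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return Invisible pipeline result.
#' @export
prongscape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: prongscape <simulate|prep|fit-climate|project|mop|fit-rsf|",
        "fit-ssf|expert|evaluate|consensus|run> [--config f] [--seed n]",
        "[--out dir] [--grid RxC] [--simulate] [--k-random K]\n")
    return(invisible(NULL))
  }
  sub <- args[1]; rest <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) && i < length(rest)) rest[i + 1] else default
  }
  cfg <- if (!is.null(getopt("--config"))) {
    utils::modifyList(default_config(), jsonlite::fromJSON(getopt("--config")))
  } else default_config()
  if (!is.null(getopt("--seed"))) cfg$seed <- as.integer(getopt("--seed"))
  if (!is.null(getopt("--out"))) cfg$out_dir <- getopt("--out")
  if (!is.null(getopt("--k-random"))) cfg$k_random <- as.integer(getopt("--k-random"))
  if (!is.null(getopt("--grid"))) {
    gg <- as.integer(strsplit(getopt("--grid"), "x")[[1]])
    cfg$grid <- list(n_rows = gg[1], n_cols = gg[2],
                     cell_size = cfg$grid$cell_size)
  }
  stage <- switch(sub, simulate = "simulate", prep = "prep",
                  `fit-climate` = "fit_climate", project = "project",
                  mop = "mop", `fit-rsf` = "fit_rsf", `fit-ssf` = "fit_ssf",
                  expert = "expert", evaluate = "evaluate",
                  consensus = "consensus", run = NULL,
                  stop("unknown subcommand: ", sub))
  res <- run_pipeline(cfg, stop_after = stage)
  cat("artifacts written to ", cfg$out_dir, "\n", sep = "")
  invisible(res)
}
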