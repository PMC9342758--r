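# app: configuration, orchestration, logging, manifest.
#
# Every stage reads its inputs from, and writes its artifacts to, the
# configured output directory in the package's plain-text formats, so stages
# are independently re-runnable from the CLI. All stage seeds derive
# deterministically from the single base seed (see stage_seed()), so one
# integer reproduces the whole synthetic study.

PIPELINE_SECTIONS <- c("seed", "output_dir", "landscape", "covariates", "rsf",
                       "telemetry", "ranges", "design", "forest", "interpret",
                       "validate")

#' Load and validate a pipeline configuration
#'
#' @param path YAML configuration file; see the bundled
#'   `system.file("extdata", "smoke_config.yaml", package = "selscape")`
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  miss <- setdiff(PIPELINE_SECTIONS, names(cfg))
  if (length(miss))
    stop("pipeline config is missing section(s): ",
         paste(miss, collapse = ", "))
  stopifnot(is.numeric(cfg$seed))
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, fun) {
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  log_stage(stage, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  res
}

cfg_landscape <- function(cfg) {
  l <- cfg$landscape
  landscape_config(l$n_rows, l$n_cols, l$cell_size %||% 30,
                   unlist(l$target_composition),
                   l$smoothing_length,
                   l$n_major_roads %||% 2, l$n_minor_roads %||% 4,
                   seed = stage_seed(cfg$seed, "landscape"))
}

cfg_rsf <- function(cfg) {
  r <- cfg$rsf
  if (identical(r$form, "threshold"))
    rsf_threshold(r$base %||% 1, r$rules)
  else
    rsf_log_linear(r$intercept %||% 0, unlist(r$coefs), r$sex_coef %||% 0)
}

stage_landscape <- function(cfg, dir) {
  lc <- cfg_landscape(cfg)
  map <- generate_landscape(lc)
  roads <- generate_roads(lc, seed = stage_seed(cfg$seed, "roads"))
  log_stage("landscape", "composition: %s",
            paste(round(composition(map), 3), collapse = " "))
  write_habitat_map(map, file.path(dir, "landscape.asc"))
  write_roads_geojson(roads, file.path(dir, "roads.geojson"))
  invisible(NULL)
}

stage_covariates <- function(cfg, dir) {
  map <- read_habitat_map(file.path(dir, "landscape.asc"))
  roads <- read_roads_geojson(file.path(dir, "roads.geojson"))
  stack <- build_covariates(map, roads, cfg$covariates$window_radius)
  write_covariates(stack, file.path(dir, "covariates"))
  invisible(NULL)
}

stage_telemetry <- function(cfg, dir) {
  map <- read_habitat_map(file.path(dir, "landscape.asc"))
  stack <- read_covariates(file.path(dir, "covariates"))
  tcfg <- cfg$telemetry
  inds <- simulate_individuals(
    tcfg$n_individuals, unlist(tcfg$sex_split %||% NULL), map,
    tcfg$mean_hr_area, seed = stage_seed(cfg$seed, "individuals"),
    n_points_mean = tcfg$n_points_mean %||% 258,
    n_points_sd = tcfg$n_points_sd %||% 36,
    n_points_min = tcfg$n_points_min %||% 30)
  rsf <- cfg_rsf(cfg)
  rec <- simulate_telemetry(inds, stack, rsf,
                            seed = stage_seed(cfg$seed, "telemetry"))
  err <- tcfg$location_error %||% 94
  rec <- apply_location_error(rec, err, map$geom,
                              seed = stage_seed(cfg$seed, "error"))
  log_stage("telemetry", "%d individuals, %d locations", nrow(inds), nrow(rec))
  write_table_csv(inds, file.path(dir, "individuals.csv"))
  write_telemetry(rec, file.path(dir, "telemetry.csv"))
  write_rsf(rsf, file.path(dir, "rsf.yaml"))
  invisible(NULL)
}

# recompute the availability regions from telemetry (deterministic), clipped
# to the map extent so available points always carry covariates
pipeline_regions <- function(cfg, dir) {
  map <- read_habitat_map(file.path(dir, "landscape.asc"))
  rec <- read_telemetry(file.path(dir, "telemetry.csv"))
  inds <- utils::read.csv(file.path(dir, "individuals.csv"),
                          stringsAsFactors = FALSE)
  ext <- as_region(map)
  sa <- clip_region(study_area(rec, inds$availability_radius[1]), ext)
  hrs <- lapply(unique(rec$id), function(id)
    clip_region(kde_home_range(rec[rec$id == id, ],
                               iso_level = cfg$ranges$iso_level %||% 0.95,
                               n_grid = cfg$ranges$n_grid %||% 200, id = id),
                ext))
  names(hrs) <- unique(rec$id)
  list(map = map, records = rec, individuals = inds, study_area = sa,
       home_ranges = hrs)
}

stage_ranges <- function(cfg, dir) {
  rg <- pipeline_regions(cfg, dir)
  write_region_geojson(rg$study_area$inner, file.path(dir, "study_area.geojson"))
  hr_dir <- file.path(dir, "homeranges")
  dir.create(hr_dir, showWarnings = FALSE)
  for (id in names(rg$home_ranges))
    write_region_geojson(rg$home_ranges[[id]]$inner,
                         file.path(hr_dir, paste0(id, ".geojson")))
  log_stage("ranges", "study area %.1f km^2, %d home ranges",
            region_area(rg$study_area$inner) / 1e6, length(rg$home_ranges))
  invisible(NULL)
}

stage_design <- function(cfg, dir) {
  rg <- pipeline_regions(cfg, dir)
  stack <- read_covariates(file.path(dir, "covariates"))
  dseed <- stage_seed(cfg$seed, "design")
  ratios <- unlist(cfg$design$ratios %||% c(1, 2, 5, 10, 20))
  tabs <- lapply(ratios, function(r)
    build_table(rg$records, stack, rg$study_area, r, "study_area",
                seed = dseed + 1000 * r))
  names(tabs) <- as.character(ratios)
  diag <- ratio_stabilization(tabs, cfg$design$epsilon %||% 0.05)
  ratio <- cfg$design$ratio %||% diag$selected_ratio
  log_stage("design", "ratio diagnostic selected 1:%d; using 1:%d",
            diag$selected_ratio, ratio)
  write_ratio_diagnostic(diag, file.path(dir, "ratio_stats.csv"))
  tab_sa <- if (as.character(ratio) %in% names(tabs)) tabs[[as.character(ratio)]]
            else build_table(rg$records, stack, rg$study_area, ratio,
                             "study_area", seed = dseed + 1000 * ratio)
  tab_hr <- build_table(rg$records, stack, rg$home_ranges, ratio,
                        "home_range", seed = dseed + 7)
  write_ua_table(tab_sa, file.path(dir, "ua_study_area.csv"))
  write_ua_table(tab_hr, file.path(dir, "ua_home_range.csv"))
  invisible(NULL)
}

cfg_grid <- function(cfg) {
  g <- cfg$forest$grid
  if (is.null(g)) return(default_forest_grid())
  gg <- expand.grid(n_trees = unlist(g$n_trees),
                    mtry = unlist(g$mtry),
                    fraction = unlist(g$sample_fraction))
  lapply(seq_len(nrow(gg)), function(i)
    forest_config(gg$n_trees[i], gg$mtry[i], gg$fraction[i],
                  min_node = cfg$forest$min_node %||% 5))
}

stage_fit <- function(cfg, dir) {
  fseed <- stage_seed(cfg$seed, "forest")
  for (scale in c("study_area", "home_range")) {
    tab <- read_ua_table(file.path(dir, paste0("ua_", scale, ".csv")))
    tr <- tune_forest(tab, cfg_grid(cfg), seed = fseed)
    log_stage("fit", "%s: chosen %d trees, mtry %d, fraction %.3f (OOB %.4f)",
              scale, tr$chosen$n_trees, tr$chosen$mtry,
              tr$chosen$sample_fraction, min(tr$oob))
    jsonlite::write_json(
      list(oob = tr$oob, chosen = unclass(tr$chosen),
           grid = lapply(tr$grid, unclass)),
      file.path(dir, paste0("tuning_", scale, ".json")),
      auto_unbox = TRUE, digits = 10)
    write_forest(tr$chosen_fit, file.path(dir, paste0("model_", scale, ".json")))
  }
  invisible(NULL)
}

# refit the chosen study-area model deterministically (the JSON model file
# omits the in-bag matrix needed for permutation importance)
refit_chosen <- function(cfg, dir, scale = "study_area") {
  tab <- read_ua_table(file.path(dir, paste0("ua_", scale, ".csv")))
  tune <- jsonlite::read_json(file.path(dir, paste0("tuning_", scale, ".json")),
                              simplifyVector = TRUE)
  cfgf <- do.call(forest_config, as.list(tune$chosen))
  list(table = tab, fit = fit_forest(tab, cfgf))
}

stage_interpret <- function(cfg, dir) {
  rc <- refit_chosen(cfg, dir, "study_area")
  stack <- read_covariates(file.path(dir, "covariates"))
  iseed <- stage_seed(cfg$seed, "interpret")
  imp <- permutation_importance(rc$fit, rc$table,
                                n_reps = cfg$interpret$n_reps %||% 1,
                                seed = iseed)
  write_table_csv(imp, file.path(dir, "importance.csv"))
  pdps <- do.call(rbind, lapply(rc$fit$predictors, function(p) {
    pc <- partial_dependence(rc$fit, rc$table, p,
                             n_grid = cfg$interpret$n_grid_pdp %||% 20)
    data.frame(predictor = p, grid = pc$grid, dependence = pc$dependence)
  }))
  write_table_csv(pdps, file.path(dir, "pdp.csv"))
  ir <- rank_interactions(rc$fit, rc$table,
                          n_bins = cfg$interpret$n_bins %||% 10)
  write_interactions(ir, file.path(dir, "interactions.csv"))
  log_stage("interpret", "top interaction: %s x %s (RMSE %.4f)",
            ir$var1[1], ir$var2[1], ir$rmse[1])
  pr <- project_map(rc$fit, stack)
  write_prediction_raster(pr, file.path(dir, "prediction.asc"))
  invisible(NULL)
}

stage_crossval <- function(cfg, dir) {
  vseed <- stage_seed(cfg$seed, "validate")
  for (scale in c("study_area", "home_range")) {
    tab <- read_ua_table(file.path(dir, paste0("ua_", scale, ".csv")))
    tune <- jsonlite::read_json(file.path(dir, paste0("tuning_", scale, ".json")),
                                simplifyVector = TRUE)
    cfgf <- do.call(forest_config, as.list(tune$chosen))
    cfgf$seed <- as.integer(vseed)
    cv <- loio_cv(tab, cfgf)
    log_stage("crossval", "%s: mean AUC %.3f +/- %.3f", scale,
              cv$mean_auc, cv$se_auc)
    write_cv_result(cv, file.path(dir, paste0("cv_", scale, ".csv")))
  }
  invisible(NULL)
}

stage_manifest <- function(cfg, dir) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  sums <- unname(tools::md5sum(file.path(dir, files)))
  jsonlite::write_json(
    list(seed = cfg$seed,
         files = stats::setNames(as.list(sums), files)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(NULL)
}

PIPELINE_STAGES <- list(
  "simulate-landscape" = stage_landscape,
  "covariates" = stage_covariates,
  "simulate-telemetry" = stage_telemetry,
  "ranges" = stage_ranges,
  "design" = stage_design,
  "fit" = stage_fit,
  "interpret" = stage_interpret,
  "crossval" = stage_crossval)

#' Run the full synthetic study end to end
#'
#' landscape -> covariates -> telemetry -> ranges -> design (ratio
#' diagnostic) -> tune/fit -> importance/PDP/interactions -> LOIO CV ->
#' projection, writing every artifact plus a checksum manifest. A second run
#' with the same configuration reproduces identical checksums.
#'
#' @param config a `pipeline_config` (or path to one)
#' @return invisibly, the manifest as a named list of md5 checksums
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(PIPELINE_STAGES))
    run_stage(nm, function() PIPELINE_STAGES[[nm]](config, dir))
  stage_manifest(config, dir)
  invisible(jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE))
}

#' Clip a region to a rectangle
#'
#' Used to intersect availability domains (buffered study areas, kernel home
#' ranges) with the covariate extent so sampled points always carry
#' covariate values.
#' @param region any region
#' @param rect a `rect_region`
#' @return a `clipped_region`
#' @export
clip_region <- function(region, rect) {
  stopifnot(inherits(rect, "rect_region"))
  structure(list(inner = region, rect = rect),
            class = c("clipped_region", "sa_region"))
}

#' @export
region_bbox.clipped_region <- function(region) {
  bi <- region_bbox(region$inner); br <- region_bbox(region$rect)
  c(xmin = unname(max(bi["xmin"], br["xmin"])),
    xmax = unname(min(bi["xmax"], br["xmax"])),
    ymin = unname(max(bi["ymin"], br["ymin"])),
    ymax = unname(min(bi["ymax"], br["ymax"])))
}
#' @export
region_contains.clipped_region <- function(region, x, y)
  region_contains(region$inner, x, y) & region_contains(region$rect, x, y)
#' @export
region_area.clipped_region <- function(region) {
  # Monte-Carlo estimate over the clipped bounding box (deterministic seed);
  # the exact area of the unclipped inner region is available directly
  bb <- region_bbox(region)
  with_seed(20260911, {
    px <- stats::runif(20000, bb["xmin"], bb["xmax"])
    py <- stats::runif(20000, bb["ymin"], bb["ymax"])
    mean(region_contains(region, px, py)) *
      (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])
  })
}
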