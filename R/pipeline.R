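PIPELINE_STAGES <- c("synth", "harmonize", "covariates", "fit", "predict",
                     "redistribute", "validate")

#' Pipeline run configuration
#'
#' Collects every knob of a full run in one place so deviations from the
#' defaults are explicit: paths, years, seeds, the forest hyperparameters
#' (500 trees, single-observation terminal nodes, all covariates per split),
#' the %RMSE denominator switch and the zero-weight fallback policy. Can be
#' loaded from a YAML or JSON file with [load_run_config()].
#'
#' @param fixture_dir Directory of inputs (see [emit_fixtures()] layout).
#' @param out_dir Directory for all stage outputs and the run report.
#' @param seed Master seed; stage seeds derive from it.
#' @param world A [world_config()] for the synth stage (defaults to
#'   `world_config(seed = seed)`).
#' @param n_trees,min_node_size,mtry Forest hyperparameters.
#' @param importance_repeats Permutation-importance repeats.
#' @param pct_denominator `%RMSE` denominator: `"mean"` or `"total"`.
#' @param iso Product file prefix.
#' @param out_crs `NULL` or `"wgs84"` for the export stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(fixture_dir, out_dir, seed = 1L, world = NULL,
                       n_trees = 500L, min_node_size = 1L, mtry = NULL,
                       importance_repeats = 5L, pct_denominator = "mean",
                       iso = "SYN", out_crs = NULL) {
  structure(list(fixture_dir = fixture_dir, out_dir = out_dir, seed = seed,
                 world = world %||% world_config(seed = seed),
                 n_trees = n_trees, min_node_size = min_node_size, mtry = mtry,
                 importance_repeats = importance_repeats,
                 pct_denominator = pct_denominator, iso = iso,
                 out_crs = out_crs),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Top-level keys mirror the [run_config()] arguments; a `world` mapping is
#' passed to [world_config()].
#'
#' @param path Config file (`.yaml`/`.yml` needs the yaml package, `.json`
#'   works always).
#' @param ... Overrides applied after the file.
#' @export
load_run_config <- function(path, ...) {
  stop_if_missing_file(path, "config")
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  if (!is.null(raw$world)) raw$world <- do.call(world_config, raw$world)
  over <- list(...)
  raw[names(over)] <- over
  do.call(run_config, raw)
}

world_manifest <- function(cfg) {
  mp <- file.path(cfg$fixture_dir, "manifest.json")
  if (!file.exists(mp))
    stop("fixtures not found in ", cfg$fixture_dir,
         "; run the 'synth' stage first")
  jsonlite::fromJSON(mp)
}

require_upstream <- function(path, stage, needed_from) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs '", path,
         "' which stage '", needed_from, "' produces; run that stage first")
  invisible(path)
}

read_harmonized <- function(cfg, year) {
  p <- file.path(cfg$out_dir, "harmonized.csv")
  require_upstream(p, "downstream", "harmonize")
  df <- utils::read.csv(p)
  df <- df[df$year == year, ]
  harmonized_census(stats::setNames(df$count, df$target_zone_id), year = year)
}

stage_synth <- function(cfg) {
  world <- generate_world(cfg$world)
  emit_fixtures(world, cfg$fixture_dir)
  man <- world_manifest(cfg)
  list(years = cfg$world$years,
       total_population = man$total_population,
       n_coarse = cfg$world$n_coarse, n_fine = cfg$world$n_fine)
}

stage_harmonize <- function(cfg) {
  man <- world_manifest(cfg)
  targets <- read_polygons_geojson(file.path(cfg$fixture_dir, "coarse_zones.geojson"))
  census <- read_census_csv(file.path(cfg$fixture_dir, "census_coarse.csv"))
  out <- NULL; rec <- list()
  for (y in man$years) {
    cy <- census[census$year == y, ]
    # source units are carried on the same polygons here; real runs may read a
    # different source zone set per year
    h <- reallocate_counts(targets, stats::setNames(cy$population, cy$unit_id),
                           targets, year = y)
    out <- rbind(out, data.frame(target_zone_id = as.integer(names(h$counts)),
                                 count = as.numeric(h$counts), year = y))
    rec[[as.character(y)]] <- list(source_total = h$source_total,
                                   harmonized_total = sum(h$counts),
                                   unallocated = h$unallocated)
  }
  utils::write.csv(out, file.path(cfg$out_dir, "harmonized.csv"), row.names = FALSE)
  jsonlite::write_json(rec, file.path(cfg$out_dir, "harmonize_report.json"),
                       auto_unbox = TRUE, digits = NA)
  rec
}

stage_covariates <- function(cfg) {
  man <- world_manifest(cfg)
  years <- man$years
  static <- list(elevation = read_raster(file.path(cfg$fixture_dir, "elevation.asc")),
                 rivers = read_raster(file.path(cfg$fixture_dir, "rivers.asc")))
  built <- lapply(years, function(y)
    read_raster(file.path(cfg$fixture_dir, paste0("built_", y, ".asc"))))
  lights <- lapply(years, function(y) {
    paths <- unlist(man$files$lights[[as.character(y)]])
    rs <- lapply(paths, read_raster)
    if (length(rs) == 1) rs[[1]] else rs
  })
  frag <- list()
  for (t in seq_along(years)) {
    stack <- build_stack(t - 1L, years, static, lights, built)
    write_stack(stack, file.path(cfg$out_dir, paste0("stack_", years[t])))
    frag[[as.character(years[t])]] <- list(n_layers = length(stack$layers),
                                           layers = names(stack$layers))
  }
  frag
}

stage_fit <- function(cfg) {
  man <- world_manifest(cfg)
  zones <- read_raster(file.path(cfg$fixture_dir, "coarse_zones.asc"))
  frag <- list()
  for (t in seq_along(man$years)) {
    y <- man$years[t]
    sd <- file.path(cfg$out_dir, paste0("stack_", y))
    require_upstream(file.path(sd, "stack_manifest.json"), "fit", "covariates")
    stack <- read_stack(sd)
    census <- read_harmonized(cfg, y)
    tab <- zonal_summarize(stack, zones, census)
    utils::write.csv(tab, file.path(cfg$out_dir, paste0("zonal_", y, ".csv")),
                     row.names = FALSE)
    model <- fit_forest(tab, seed = cfg$seed + t,
                        n_trees = cfg$n_trees,
                        min_node_size = cfg$min_node_size, mtry = cfg$mtry)
    err <- oob_error(model, tab)
    imp <- permutation_importance(model, tab,
                                  n_repeats = cfg$importance_repeats,
                                  seed = cfg$seed + 100 + t)
    saveRDS(list(model = model, table = tab),
            file.path(cfg$out_dir, paste0("model_", y, ".rds")))
    write_model_card(model, err, imp, y,
                     file.path(cfg$out_dir, paste0("model_card_", y, ".json")))
    frag[[as.character(y)]] <- list(n_zones = nrow(tab),
                                    mse_log = err$mse_log,
                                    variance_explained = err$variance_explained,
                                    top_covariate = names(which.max(unclass(imp))))
  }
  frag
}

stage_predict <- function(cfg) {
  man <- world_manifest(cfg)
  frag <- list()
  for (y in man$years) {
    mp <- file.path(cfg$out_dir, paste0("model_", y, ".rds"))
    require_upstream(mp, "predict", "fit")
    model <- readRDS(mp)$model
    stack <- read_stack(file.path(cfg$out_dir, paste0("stack_", y)))
    w <- predict_density_surface(model, stack)
    write_raster(w, file.path(cfg$out_dir, paste0("weights_", y, ".asc")))
    frag[[as.character(y)]] <- list(usable_pixels = sum(!is.na(w$values)))
  }
  frag
}

stage_redistribute <- function(cfg) {
  man <- world_manifest(cfg)
  zones <- read_raster(file.path(cfg$fixture_dir, "coarse_zones.asc"))
  frag <- list()
  for (y in man$years) {
    wp <- file.path(cfg$out_dir, paste0("weights_", y, ".asc"))
    require_upstream(wp, "redistribute", "predict")
    weights <- read_raster(wp)
    census <- read_harmonized(cfg, y)
    ppp <- redistribute(census, weights, zones, year = y)
    res <- conservation_residuals(ppp, zones, census)
    exp_rep <- export_products(ppp, cfg$out_dir, iso = cfg$iso, year = y,
                               out_crs = cfg$out_crs)
    jsonlite::write_json(as.list(res),
                         file.path(cfg$out_dir, paste0("conservation_", y, ".json")),
                         auto_unbox = TRUE, digits = NA)
    frag[[as.character(y)]] <- list(max_conservation_residual = max(res),
                                    total = exp_rep$report$working_total,
                                    n_fallback_zones = length(attr(ppp, "fallback_zones")))
  }
  max_res <- max(vapply(frag, `[[`, 0, "max_conservation_residual"))
  if (max_res > 1e-6)
    stop("conservation violated: max per-zone relative residual ",
         format(max_res), " exceeds 1e-6")
  frag
}

stage_validate <- function(cfg) {
  man <- world_manifest(cfg)
  val_zones <- read_raster(file.path(cfg$fixture_dir, "fine_zones.asc"))
  observed <- read_census_csv(file.path(cfg$fixture_dir, "census_fine.csv"))
  all_metrics <- NULL
  frag <- list()
  for (y in man$years) {
    pp <- file.path(cfg$out_dir, sprintf("%s_ppp_%s.asc", cfg$iso, y))
    require_upstream(pp, "validate", "redistribute")
    ppp <- read_raster(pp)
    v <- validate_population(ppp, val_zones, observed[observed$year == y, ],
                             pct_denominator = cfg$pct_denominator)
    m <- cbind(year = y, v$metrics)
    all_metrics <- rbind(all_metrics, m)
    utils::write.csv(v$table,
                     file.path(cfg$out_dir, paste0("obs_vs_pred_", y, ".csv")),
                     row.names = FALSE)
    frag[[as.character(y)]] <- split(v$metrics[, c("rmse", "rmse_per_area",
                                                   "pct_rmse", "mae", "mad")],
                                     v$metrics$scale)
  }
  utils::write.csv(all_metrics, file.path(cfg$out_dir, "validation_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(frag, file.path(cfg$out_dir, "validation_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  frag
}

#' Run one pipeline stage
#'
#' Stages: `synth` (generate + emit the synthetic world), `harmonize`,
#' `covariates`, `fit`, `predict`, `redistribute`, `validate`. Each stage
#' reads its upstream outputs from disk (an actionable error names the stage
#' to run first when they are missing), writes its own outputs under
#' `cfg$out_dir`, appends a JSON report fragment, and returns the fragment.
#'
#' @param stage Stage name.
#' @param cfg A [run_config()].
#' @return The report fragment (list), invisibly.
#' @export
run_stage <- function(stage, cfg) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  frag <- switch(stage,
                 synth = stage_synth(cfg),
                 harmonize = stage_harmonize(cfg),
                 covariates = stage_covariates(cfg),
                 fit = stage_fit(cfg),
                 predict = stage_predict(cfg),
                 redistribute = stage_redistribute(cfg),
                 validate = stage_validate(cfg))
  elapsed <- proc.time()[["elapsed"]] - t0
  frag <- list(stage = stage, elapsed_s = round(elapsed, 3), detail = frag)
  jsonlite::write_json(frag,
                       file.path(cfg$out_dir, paste0("report_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  dp_log("stage %-12s done in %6.1f s", stage, elapsed)
  invisible(frag)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order and assembles `run_report.json`
#' (seeds, per-stage fragments, the maximum conservation residual). The run
#' fails — with a nonzero exit under `Rscript` — if any zone's redistribution
#' residual exceeds 1e-6 relative.
#'
#' @param cfg A [run_config()].
#' @param stages Stage names to run, in pipeline order (default all).
#' @return The run report (list), invisibly.
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  frags <- lapply(stages, run_stage, cfg = cfg)
  names(frags) <- stages
  max_res <- NA_real_
  if ("redistribute" %in% stages)
    max_res <- max(vapply(frags$redistribute$detail, `[[`, 0,
                          "max_conservation_residual"))
  report <- list(seed = cfg$seed,
                 n_trees = cfg$n_trees, min_node_size = cfg$min_node_size,
                 mtry = cfg$mtry %||% "all",
                 pct_denominator = cfg$pct_denominator,
                 max_conservation_residual = max_res,
                 stages = frags)
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
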