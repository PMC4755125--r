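#' Covariate stacks for every year of a synthetic world
#'
#' Convenience wrapper over [build_stack()]: returns one stack per year, each
#' with the static layers, that year's lights composite and the built-distance
#' layers for the year and all preceding years.
#'
#' @param world A [generate_world()] result.
#' @return List of [covariate_stack()] objects, one per year.
#' @export
world_stacks <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- world$config
  static <- list(elevation = world$elevation, rivers = world$rivers)
  lapply(seq_along(cfg$years), function(t)
    build_stack(t - 1L, cfg$years, static, world$lights, world$built))
}

#' Harmonized coarse census of a synthetic world for one year
#' @param world A [generate_world()] result.
#' @param year Year label.
#' @export
world_harmonized <- function(world, year) {
  cc <- world$census_coarse
  cy <- cc[cc$year == year, ]
  if (nrow(cy) == 0) stop("no census for year ", year)
  harmonized_census(stats::setNames(cy$population, cy$unit_id), year = year)
}

#' Pearson correlation between two rasters over shared pixels
#' @param a,b Aligned `grid_raster` objects.
#' @export
pixel_correlation <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters are not aligned")
  ok <- !is.na(a$values) & !is.na(b$values)
  stats::cor(a$values[ok], b$values[ok])
}

# swap the current-year built-distance layer name for a year-independent one,
# dropping lagged layers, so rows from different years can be pooled
common_covariate_stack <- function(stack, year) {
  keep <- c("lights", "elevation", "slope", "dist_water",
            paste0("built_dist_", year))
  layers <- stack$layers[keep]
  names(layers) <- c("lights", "elevation", "slope", "dist_water", "built_dist")
  covariate_stack(year, layers)
}

#' Per-year versus pooled model comparison
#'
#' Quantifies the case for fitting each census year independently: fits (a)
#' one forest per year on that year's zonal table and (b) a single pooled
#' forest on all years' rows over the covariates shared by every year
#' (lights, elevation, slope, distance to water, current-year built
#' distance), then redistributes the harmonized counts with each weighting
#' layer and correlates the resulting people-per-pixel surface with the true
#' surface. When the density-distance relationship drifts over time
#' (`regime = "timevary"`), the pooled model is structurally misspecified and
#' the per-year correlations win; when it is static the two are close.
#'
#' @param world A [generate_world()] result.
#' @param n_trees,min_node_size Forest hyperparameters.
#' @param seed Seed for the forest fits.
#' @return Data frame with one row per year: `cor_per_year`, `cor_pooled`.
#' @export
temporal_fit_comparison <- function(world, n_trees = 500L, min_node_size = 1L,
                                    seed = 1L) {
  cfg <- world$config
  stacks <- world_stacks(world)
  zones <- world$coarse_zones
  ny <- length(cfg$years)

  tabs_full <- vector("list", ny)
  tabs_common <- vector("list", ny)
  stacks_common <- vector("list", ny)
  for (t in seq_len(ny)) {
    census <- world_harmonized(world, cfg$years[t])
    tabs_full[[t]] <- zonal_summarize(stacks[[t]], zones, census)
    stacks_common[[t]] <- common_covariate_stack(stacks[[t]], cfg$years[t])
    tabs_common[[t]] <- zonal_summarize(stacks_common[[t]], zones, census)
  }
  pooled_tab <- do.call(rbind, lapply(tabs_common, as.data.frame))
  attr(pooled_tab, "covariates") <- attr(tabs_common[[1]], "covariates")
  class(pooled_tab) <- c("zonal_table", "data.frame")
  pooled_model <- fit_forest(pooled_tab, seed = seed, n_trees = n_trees,
                             min_node_size = min_node_size)

  res <- data.frame(year = cfg$years, cor_per_year = NA_real_,
                    cor_pooled = NA_real_)
  for (t in seq_len(ny)) {
    census <- world_harmonized(world, cfg$years[t])
    truth <- world$ppp_true[[t]]

    m_t <- fit_forest(tabs_full[[t]], seed = seed + t, n_trees = n_trees,
                      min_node_size = min_node_size)
    w_t <- predict_density_surface(m_t, stacks[[t]])
    ppp_t <- redistribute(census, w_t, zones)
    res$cor_per_year[t] <- pixel_correlation(ppp_t, truth)

    w_p <- predict_density_surface(pooled_model, stacks_common[[t]])
    ppp_p <- redistribute(census, w_p, zones)
    res$cor_pooled[t] <- pixel_correlation(ppp_p, truth)
  }
  res
}
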