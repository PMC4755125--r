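#' Aggregate a gridded population surface to validation units
#'
#' Sums people-per-pixel over each validation zone, the standard check of a
#' dasymetric product against finer census counts than those it was built
#' from.
#'
#' @param ppp People-per-pixel `grid_raster`.
#' @param val_zones Zone-id `grid_raster` aligned with `ppp`.
#' @return Data frame with `zone_id`, `pred_count`, `pixel_count`.
#' @export
aggregate_to_units <- function(ppp, val_zones) {
  stopifnot(inherits(ppp, "grid_raster"), inherits(val_zones, "grid_raster"))
  if (!same_grid(ppp, val_zones)) stop("ppp and validation zones are not aligned")
  zv <- val_zones$values
  inz <- which(!is.na(zv))
  ids <- sort(unique(zv[inz]))
  zf <- factor(zv[inz], levels = ids)
  v <- ppp$values[inz]
  v[is.na(v)] <- 0
  data.frame(zone_id = ids,
             pred_count = as.numeric(rowsum(v, zf)),
             pixel_count = as.integer(table(zf)))
}

#' Population density of a unit in people per pixel
#' @param count People in the unit.
#' @param pixel_count Pixels in the unit (>= 1).
#' @export
unit_density <- function(count, pixel_count) {
  if (any(pixel_count < 1)) stop("pixel_count must be >= 1")
  count / pixel_count
}

#' Validation error metrics on counts or densities
#'
#' Computes the error suite comparing predicted with observed per-unit values:
#' \itemize{
#'   \item `rmse = sqrt(mean((pred - obs)^2))`
#'   \item `mae = mean(|pred - obs|)`
#'   \item `mad = median(|pred - obs|)` (robust to the few very large errors
#'     typical of highly skewed population counts)
#'   \item `pct_rmse = 100 * rmse / mean(obs)` by default, or
#'     `100 * rmse / sum(obs)` with `pct_denominator = "total"`
#'   \item `rmse_per_area`: RMSE of the per-unit density errors
#'     `(pred - obs) / pixel_count` (given `pixel_counts`) — algebraically the
#'     density-scale RMSE, so the counts-scale `rmse_per_area` equals the
#'     densities-scale `rmse`.
#' }
#'
#' @param obs,pred Numeric vectors of equal length >= 1.
#' @param pixel_counts Optional per-unit pixel counts (> 0) for
#'   `rmse_per_area`.
#' @param scale Label: `"counts"` or `"densities"`.
#' @param pct_denominator `"mean"` (default) or `"total"`.
#' @return List of class `validation_metrics`.
#' @export
error_metrics <- function(obs, pred, pixel_counts = NULL,
                          scale = c("counts", "densities"),
                          pct_denominator = c("mean", "total")) {
  scale <- match.arg(scale)
  pct_denominator <- match.arg(pct_denominator)
  if (length(obs) != length(pred) || length(obs) < 1)
    stop("obs and pred must be equal-length vectors of length >= 1")
  err <- pred - obs
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  mad <- stats::median(abs(err))
  denom <- if (pct_denominator == "mean") mean(obs) else sum(obs)
  pct_rmse <- if (denom > 0) 100 * rmse / denom else {
    dp_log("error_metrics: observed total is zero; pct_rmse undefined")
    NA_real_
  }
  rmse_per_area <- NA_real_
  if (!is.null(pixel_counts)) {
    if (any(pixel_counts <= 0)) stop("pixel_counts must be > 0")
    rmse_per_area <- sqrt(mean((err / pixel_counts)^2))
  }
  structure(list(rmse = rmse, rmse_per_area = rmse_per_area,
                 pct_rmse = pct_rmse, mae = mae, mad = mad,
                 n_units = length(obs), scale = scale),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("<validation_metrics> %s over %d units\n", x$scale, x$n_units))
  cat(sprintf("  RMSE %.5g | RMSE/Area %.5g | %%RMSE %.4g | MAE %.5g | MAD %.5g\n",
              x$rmse, x$rmse_per_area, x$pct_rmse, x$mae, x$mad))
  invisible(x)
}

#' Validate a population surface against observed unit counts
#'
#' Aggregates the surface to the validation zones, joins the observed counts,
#' and returns the full metric suite on both the counts and the densities
#' scale (one row each), plus the observed-vs-predicted table for plotting.
#'
#' @param ppp People-per-pixel `grid_raster`.
#' @param val_zones Validation zone-id `grid_raster`.
#' @param observed Data frame with `unit_id` and `population` at the
#'   validation level.
#' @param pct_denominator Passed to [error_metrics()].
#' @return List with `metrics` (data.frame, rows counts/densities) and
#'   `table` (per-unit observed/predicted).
#' @export
validate_population <- function(ppp, val_zones, observed,
                                pct_denominator = "mean") {
  agg <- aggregate_to_units(ppp, val_zones)
  m <- match(agg$zone_id, observed$unit_id)
  if (anyNA(m))
    stop("observed counts missing for validation zone id(s): ",
         paste(agg$zone_id[is.na(m)], collapse = ", "))
  obs <- observed$population[m]
  mc <- error_metrics(obs, agg$pred_count, agg$pixel_count,
                      scale = "counts", pct_denominator = pct_denominator)
  md <- error_metrics(unit_density(obs, agg$pixel_count),
                      unit_density(agg$pred_count, agg$pixel_count),
                      scale = "densities", pct_denominator = pct_denominator)
  metrics <- rbind(as.data.frame(unclass(mc), stringsAsFactors = FALSE),
                   as.data.frame(unclass(md), stringsAsFactors = FALSE))
  list(metrics = metrics,
       table = data.frame(zone_id = agg$zone_id, observed = obs,
                          predicted = agg$pred_count,
                          pixel_count = agg$pixel_count))
}
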