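#' Dasymetric redistribution of harmonized counts to pixels
#'
#' The pipeline's central operation and its central invariant: each zone's
#' count is spread over its pixels proportionally to the weighting layer,
#' `ppp(pixel) = count(zone) * w(pixel) / sum(w over the zone's usable
#' pixels)`, so the pixel sum over every zone equals its harmonized count
#' exactly (up to floating point). Zones whose usable weights sum to zero (or
#' with no usable weight pixels at all) fall back to uniform allocation over
#' all their pixels, with a logged warning, so census mass is never lost.
#' In-zone pixels with `NA` weight receive 0 when the zone has usable weight;
#' pixels outside every zone are `NA`.
#'
#' @param census A [harmonized_census()]; every zone id present in `zones`
#'   must have a count (error otherwise). Census zones absent from the raster
#'   are reported in the `undistributed` attribute.
#' @param weights A weighting-layer `grid_raster`
#'   ([predict_density_surface()] output), aligned with `zones`.
#' @param zones Zone-id `grid_raster`.
#' @param year Year label attached to the result.
#' @return A people-per-pixel `grid_raster` with attributes `year`,
#'   `fallback_zones` and `undistributed`.
#' @export
redistribute <- function(census, weights, zones, year = census$year) {
  stopifnot(inherits(census, "harmonized_census"),
            inherits(weights, "grid_raster"), inherits(zones, "grid_raster"))
  if (!same_grid(weights, zones)) stop("weights and zones are not aligned")
  zv <- zones$values
  wv <- weights$values
  inz <- which(!is.na(zv))
  ids <- sort(unique(zv[inz]))
  missing <- setdiff(as.character(ids), names(census$counts))
  if (length(missing) > 0)
    stop("no census count for zone id(s): ", paste(missing, collapse = ", "))
  undistributed <- census$counts[setdiff(names(census$counts), as.character(ids))]
  if (length(undistributed) > 0 && any(undistributed > 0))
    dp_log("redistribute: %d census zone(s) absent from raster; %.6g people undistributed",
           sum(undistributed > 0), sum(undistributed))

  zf <- factor(zv[inz], levels = ids)
  w0 <- wv[inz]
  w0[is.na(w0)] <- 0
  wsum <- as.numeric(rowsum(w0, zf))            # usable weight total per zone
  npix <- as.integer(table(zf))
  cnt <- as.numeric(census$counts[as.character(ids)])

  zi <- as.integer(zf)
  fallback <- wsum <= 0
  if (any(fallback))
    dp_log("redistribute: uniform fallback for %d zero-weight zone(s)", sum(fallback))
  val <- ifelse(fallback[zi], cnt[zi] / npix[zi], cnt[zi] * w0 / wsum[zi])

  out <- matrix(NA_real_, nrow(zv), ncol(zv))
  out[inz] <- val
  ppp <- with_values(zones, out)
  attr(ppp, "year") <- year
  attr(ppp, "fallback_zones") <- ids[fallback]
  attr(ppp, "undistributed") <- undistributed
  ppp
}

#' Per-zone conservation residuals
#'
#' Relative difference between each zone's pixel sum and its harmonized count;
#' the pipeline requires the maximum to stay below 1e-6.
#'
#' @param ppp People-per-pixel `grid_raster` from [redistribute()].
#' @param zones Zone-id `grid_raster`.
#' @param census The [harmonized_census()] that was redistributed.
#' @return Named numeric vector of relative residuals.
#' @export
conservation_residuals <- function(ppp, zones, census) {
  zv <- zones$values
  inz <- which(!is.na(zv))
  ids <- sort(unique(zv[inz]))
  sums <- as.numeric(rowsum(ppp$values[inz], factor(zv[inz], levels = ids)))
  cnt <- as.numeric(census$counts[as.character(ids)])
  stats::setNames(abs(sums - cnt) / pmax(cnt, 1), as.character(ids))
}

#' Convert people per pixel to people per hectare
#'
#' `pph = ppp / (pixel area in hectares)`; on a 100 m grid (1 ha pixels) the
#' two surfaces coincide.
#'
#' @param ppp People-per-pixel `grid_raster`.
#' @return People-per-hectare `grid_raster`.
#' @export
ppp_to_pph <- function(ppp) {
  stopifnot(inherits(ppp, "grid_raster"))
  area_ha <- ppp$pixel_size^2 / 1e4
  with_values(ppp, ppp$values / area_ha)
}

#' Tangent-plane projection pair for final export
#'
#' A single configured projection pair between the working metric grid and
#' WGS84 geographic coordinates: a local equirectangular tangent plane at
#' (`lon0`, `lat0`) on a spherical earth. Adequate for study-area-sized
#' domains; all analysis happens on the working grid and export is a
#' convenience copy.
#'
#' @param lon0,lat0 Tangent point in degrees.
#' @param radius Earth radius in metres.
#' @return List with `forward(lon, lat) -> (x, y)` and
#'   `inverse(x, y) -> (lon, lat)`.
#' @export
local_projection <- function(lon0 = 110, lat0 = 30, radius = 6378137) {
  k <- pi / 180
  list(
    lon0 = lon0, lat0 = lat0, radius = radius,
    forward = function(lon, lat)
      list(x = radius * cos(lat0 * k) * (lon - lon0) * k,
           y = radius * (lat - lat0) * k),
    inverse = function(x, y)
      list(lon = lon0 + x / (radius * cos(lat0 * k)) / k,
           lat = lat0 + y / radius / k)
  )
}

# nearest-neighbour reprojection of a working-grid raster onto a geographic grid
reproject_to_geographic <- function(g, proj = local_projection(), pixel_deg = NULL) {
  ext <- grid_extent(g)
  ll <- proj$inverse(c(ext["xmin"], ext["xmax"]), c(ext["ymin"], ext["ymax"]))
  # square-in-degrees pixels sized so the ground area per output pixel matches
  # the source pixel area at the tangent latitude; nearest-neighbour copying of
  # per-pixel counts then conserves the total to within discretisation error
  if (is.null(pixel_deg))
    pixel_deg <- g$pixel_size / proj$radius * 180 / pi /
      sqrt(cos(proj$lat0 * pi / 180))
  nc <- ceiling((ll$lon[2] - ll$lon[1]) / pixel_deg)
  nr <- ceiling((ll$lat[2] - ll$lat[1]) / pixel_deg)
  lon <- ll$lon[1] + (seq_len(nc) - 0.5) * pixel_deg
  lat <- ll$lat[2] - (seq_len(nr) - 0.5) * pixel_deg
  xy <- proj$forward(matrix(lon, nr, nc, byrow = TRUE), matrix(lat, nr, nc))
  col <- floor((xy$x - g$origin_x) / g$pixel_size) + 1L
  row <- floor((g$origin_y - xy$y) / g$pixel_size) + 1L
  d <- dim(g$values)
  ok <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1]
  out <- matrix(NA_real_, nr, nc)
  out[ok] <- g$values[cbind(row[ok], col[ok])]
  grid_raster(out, origin_x = ll$lon[1], origin_y = ll$lat[2],
              pixel_size = pixel_deg, crs = "wgs84", nodata = g$nodata)
}

#' Export people-per-pixel and people-per-hectare products
#'
#' Writes `{iso}_ppp_{year}.asc` and `{iso}_pph_{year}.asc` on the working
#' grid (the mass-true reference product) and, when `out_crs = "wgs84"`, a
#' nearest-neighbour geographic copy of each (`*_wgs84.asc`). Reprojected
#' totals may drift slightly from the working-grid totals; both are recorded
#' in the returned report so the bookkeeping is explicit.
#'
#' @param ppp People-per-pixel `grid_raster` from [redistribute()].
#' @param out_dir Output directory.
#' @param iso Dataset prefix (ISO-style code).
#' @param year Year label.
#' @param out_crs `NULL` (working CRS only) or `"wgs84"`.
#' @param proj Projection pair from [local_projection()].
#' @return List with file paths and a mass report, invisibly.
#' @export
export_products <- function(ppp, out_dir, iso = "SYN", year,
                            out_crs = NULL, proj = local_projection()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pph <- ppp_to_pph(ppp)
  p_ppp <- file.path(out_dir, sprintf("%s_ppp_%s.asc", iso, year))
  p_pph <- file.path(out_dir, sprintf("%s_pph_%s.asc", iso, year))
  write_raster(ppp, p_ppp)
  write_raster(pph, p_pph)
  files <- list(ppp = p_ppp, pph = p_pph)
  report <- list(working_total = sum(ppp$values, na.rm = TRUE))
  if (!is.null(out_crs)) {
    if (identical(out_crs, ppp$crs)) {
      files$ppp_export <- p_ppp            # identity reprojection: same grids
      files$pph_export <- p_pph
      report$export_total <- report$working_total
    } else if (identical(out_crs, "wgs84")) {
      gp <- reproject_to_geographic(ppp, proj)
      gh <- reproject_to_geographic(pph, proj)
      files$ppp_export <- file.path(out_dir, sprintf("%s_ppp_%s_wgs84.asc", iso, year))
      files$pph_export <- file.path(out_dir, sprintf("%s_pph_%s_wgs84.asc", iso, year))
      write_raster(gp, files$ppp_export)
      write_raster(gh, files$pph_export)
      report$export_total <- sum(gp$values, na.rm = TRUE)
    } else stop("unsupported output CRS: ", out_crs)
  }
  invisible(list(files = files, report = report))
}
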