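# ---- exact Euclidean distance transform -------------------------------------
#
# Separable lower-envelope algorithm on squared distances: each 1D pass
# computes, exactly, min_j (f[j] + (i-j)^2) by maintaining the lower envelope
# of the parabolas rooted at the feature cells. Two passes (columns then rows)
# give the exact 2D squared EDT. A large finite constant stands in for
# +infinity so the parabola intersections stay well defined.

.dt1d <- function(f) {
  n <- length(f)
  if (n == 1) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# feature: logical matrix (NA treated as non-feature); returns metres
.edt <- function(feature, pixel_size) {
  nr <- nrow(feature); nc <- ncol(feature)
  big <- (nr * nr + nc * nc + 1) * 4
  f <- matrix(big, nr, nc)
  f[which(feature)] <- 0
  g <- matrix(apply(f, 2, .dt1d), nr, nc)
  d2 <- t(apply(g, 1, .dt1d))
  if (nc == 1) d2 <- t(d2)
  sqrt(d2) * pixel_size
}

#' Signed Euclidean distance to the built-area edge
#'
#' For non-built cells, the (positive) centre-to-centre Euclidean distance to
#' the nearest built cell; for built cells, minus the distance to the nearest
#' non-built cell. The sign therefore partitions exactly along the input mask
#' and zero never occurs (magnitudes are at least one pixel). `NA` cells take
#' no part in the search and stay `NA`.
#'
#' @param built A `grid_raster` with values in {0, 1, NA}; at least one built
#'   and one non-built cell are required (otherwise the edge is undefined).
#' @return A `grid_raster` of signed distances in metres.
#' @export
signed_distance_to_edge <- function(built) {
  stopifnot(inherits(built, "grid_raster"))
  v <- built$values
  ok <- !is.na(v)
  if (!all(v[ok] %in% c(0, 1))) stop("built mask must contain only 0, 1, NA")
  if (!any(v[ok] == 1)) stop("edge undefined: no built cells")
  if (!any(v[ok] == 0)) stop("edge undefined: all cells built")
  d_to_built <- .edt(!is.na(v) & v == 1, built$pixel_size)
  d_to_open  <- .edt(!is.na(v) & v == 0, built$pixel_size)
  out <- ifelse(v == 1, -d_to_open, d_to_built)
  out[!ok] <- NA_real_
  with_values(built, out)
}

#' Euclidean distance to the nearest feature cell
#'
#' Feature cells map to 0; everywhere else the centre-to-centre distance to the
#' nearest feature cell, in metres. Used for the distance-to-rivers covariate.
#'
#' @param features A `grid_raster` with values in {0, 1, NA}; at least one
#'   feature (1) cell required.
#' @return A `grid_raster` of distances in metres.
#' @export
distance_to_features <- function(features) {
  stopifnot(inherits(features, "grid_raster"))
  v <- features$values
  ok <- !is.na(v)
  if (!any(v[ok] == 1)) stop("no feature cells")
  out <- .edt(!is.na(v) & v == 1, features$pixel_size)
  out[!ok] <- NA_real_
  with_values(features, out)
}

#' Terrain slope from elevation (Horn estimator)
#'
#' 3x3 finite differences with the Horn weighting; border cells use edge
#' replication. Result in degrees. Cells with any `NA` neighbour are `NA`.
#'
#' @param dem A `grid_raster` of elevations in metres, at least 3x3.
#' @return A `grid_raster` of slopes in degrees.
#' @export
slope_from_elevation <- function(dem) {
  stopifnot(inherits(dem, "grid_raster"))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("dem must be at least 3x3")
  p <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  rI <- 1 + seq_len(nr); cI <- 1 + seq_len(nc)
  a <- p[rI - 1, cI - 1]; b <- p[rI - 1, cI]; cc_ <- p[rI - 1, cI + 1]
  d <- p[rI, cI - 1];                         f <- p[rI, cI + 1]
  g <- p[rI + 1, cI - 1]; h <- p[rI + 1, cI]; i <- p[rI + 1, cI + 1]
  px <- dem$pixel_size
  dzdx <- ((cc_ + 2 * f + i) - (a + 2 * d + g)) / (8 * px)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc_)) / (8 * px)
  with_values(dem, atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
}

#' Composite lights-at-night layers by cellwise averaging
#'
#' When two satellites image the same year, the model input is their cellwise
#' arithmetic mean. A cell is `NA` iff it is `NA` in any input.
#'
#' @param rasters List of aligned `grid_raster` objects (length >= 1).
#' @return A `grid_raster`.
#' @export
composite_lights <- function(rasters) {
  if (length(rasters) < 1) stop("at least one lights raster required")
  g1 <- rasters[[1]]
  for (g in rasters[-1])
    if (!same_grid(g1, g)) stop("lights rasters are not grid-aligned")
  if (length(rasters) == 1) return(g1)
  with_values(g1, Reduce(`+`, lapply(rasters, `[[`, "values")) / length(rasters))
}

#' Per-year covariate stack
#'
#' @param year Year label.
#' @param layers Named list of aligned `grid_raster` layers.
#' @param tags Per-layer `"continuous"`/`"categorical"` flags (named like
#'   `layers`).
#' @return Object of class `covariate_stack`.
#' @export
covariate_stack <- function(year, layers, tags = NULL) {
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named")
  for (g in layers[-1])
    if (!same_grid(layers[[1]], g)) stop("stack layers must share one grid")
  if (is.null(tags)) tags <- stats::setNames(rep("continuous", length(layers)), names(layers))
  structure(list(year = year, layers = layers, tags = tags),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> year %s: %d layers (%s)\n",
              as.character(x$year), length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Build the covariate stack for one model year
#'
#' Assembles, on one aligned grid: the year's lights composite, elevation and
#' its derived slope, distance to water features, and a signed
#' distance-to-built-edge layer for the current year *and every preceding
#' year* (the built-area-history covariates). Layer order is deterministic:
#' lights, elevation, slope, dist_water, then built distances oldest to
#' newest. So year index 0 carries exactly one built-distance layer (5 layers
#' total with the three static ones and lights) and year index t carries
#' t + 1 of them.
#'
#' @param year_index 0-based index into `years`.
#' @param years Ordered vector of year labels.
#' @param static Named list with `elevation` (continuous `grid_raster`) and
#'   `rivers` (binary water-feature mask).
#' @param lights Per-year list: each element a `grid_raster` or a list of them
#'   (several satellites, composited by [composite_lights()]). Indexed 1..t+1
#'   in year order.
#' @param built Per-year list of binary built-extent masks, indexed 1..t+1 in
#'   year order; masks must be available for every year index <= `year_index`.
#' @return A [covariate_stack()] for `years[year_index + 1]`.
#' @export
build_stack <- function(year_index, years, static, lights, built) {
  if (year_index < 0 || year_index >= length(years))
    stop("year_index out of range")
  need <- year_index + 1
  if (length(built) < need || any(vapply(built[seq_len(need)], is.null, TRUE)))
    stop("missing built mask for a year index <= ", year_index)
  if (length(lights) < need || is.null(lights[[need]]))
    stop("missing lights for year index ", year_index)
  li <- lights[[need]]
  lights_year <- if (inherits(li, "grid_raster")) li else composite_lights(li)

  rasters <- c(list(lights_year, static$elevation, static$rivers),
               built[seq_len(need)])
  tags <- c("continuous", "continuous", "categorical",
            rep("categorical", need))
  aligned <- align_stack(rasters, tags)

  layers <- list(
    lights = aligned[[1]],
    elevation = aligned[[2]],
    slope = slope_from_elevation(aligned[[2]]),
    dist_water = distance_to_features(aligned[[3]])
  )
  for (k in seq_len(need)) {
    layers[[paste0("built_dist_", years[k])]] <-
      signed_distance_to_edge(aligned[[3 + k]])
  }
  covariate_stack(years[need], layers)
}

#' Write a covariate stack (layers + JSON manifest)
#' @param stack A [covariate_stack()].
#' @param dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(stack$layers)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_raster(stack$layers[[nm]], p)
    paths[nm] <- p
  }
  manifest <- list(year = stack$year, layers = as.list(paths),
                   tags = as.list(stack$tags))
  mp <- file.path(dir, "stack_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a covariate stack written by [write_stack()]
#' @param dir Directory holding the layers and `stack_manifest.json`.
#' @export
read_stack <- function(dir) {
  mp <- file.path(dir, "stack_manifest.json")
  stop_if_missing_file(mp, "stack manifest")
  manifest <- jsonlite::fromJSON(mp)
  layers <- lapply(manifest$layers, read_raster)
  covariate_stack(manifest$year, layers,
                  tags = unlist(manifest$tags) %||% NULL)
}
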