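#' Gridded raster with georeferencing
#'
#' The carrier for every covariate and output surface: a 2D numeric matrix on a
#' square-pixel projected grid. Row 1 is the northernmost row, column 1 the
#' westernmost column; `origin_x`/`origin_y` give the projected coordinates of
#' the outer (north-west) corner of cell (1,1), and extents are half-open.
#' Missing cells are stored as `NA` in memory; the `nodata` sentinel is used
#' only on disk.
#'
#' @param values Numeric matrix (rows = north to south).
#' @param origin_x,origin_y Projected coordinates (working-CRS units, metres)
#'   of the north-west corner of the grid.
#' @param pixel_size Side of a (square) pixel in working-CRS units; must be > 0.
#' @param crs Free-text identifier of the coordinate reference system.
#' @param nodata Sentinel value used when the raster is written to disk.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin_x = 0, origin_y = nrow(values) * pixel_size,
                        pixel_size = 100, crs = "local-m", nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         pixel_size = pixel_size, crs = crs, nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d @ %g m, crs '%s'\n",
              nrow(v), ncol(v), x$pixel_size, x$crs))
  cat(sprintf("  origin (%g, %g); %d NA cells; range [%g, %g]\n",
              x$origin_x, x$origin_y, sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Grid extent as c(xmin, xmax, ymin, ymax)
#' @param g A `grid_raster`.
#' @export
grid_extent <- function(g) {
  d <- dim(g$values)
  c(xmin = g$origin_x, xmax = g$origin_x + d[2] * g$pixel_size,
    ymin = g$origin_y - d[1] * g$pixel_size, ymax = g$origin_y)
}

#' Pixel-centre coordinates
#'
#' @param g A `grid_raster`.
#' @return List with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south).
#' @export
cell_centers <- function(g) {
  d <- dim(g$values)
  list(x = g$origin_x + (seq_len(d[2]) - 0.5) * g$pixel_size,
       y = g$origin_y - (seq_len(d[1]) - 0.5) * g$pixel_size)
}

#' Do two rasters share the same grid?
#' @param a,b `grid_raster` objects.
#' @param tol Absolute tolerance on origins and pixel size.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    identical(a$crs, b$crs)
}

# carry a new value matrix on the same grid
with_values <- function(g, values) {
  grid_raster(values, g$origin_x, g$origin_y, g$pixel_size, g$crs, g$nodata)
}

crs_sidecar <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".prj")

#' Read a single-band ESRI ASCII grid raster
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header (the `dx`/`dy` extension for rectangular pixels is recognised and
#' rejected, since the package requires square pixels). A plain-text `.prj`
#' sidecar, when present, supplies the CRS label.
#'
#' @param path Path to the `.asc` file.
#' @return A `grid_raster`; nodata cells are returned as `NA` and the sentinel
#'   is preserved in the `nodata` field.
#' @export
read_raster <- function(path) {
  stop_if_missing_file(path, "raster")
  head_lines <- readLines(path, n = 8L, warn = FALSE)
  hdr <- list(); n_hdr <- 0L
  for (ln in head_lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (k in c("ncols", "nrows"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header (missing ", k, "): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    if (is.null(hdr$dx) || is.null(hdr$dy) || hdr$dx != hdr$dy)
      stop("non-square pixels are not supported: ", path)
    px <- hdr$dx
  } else if (!is.null(hdr$cellsize)) {
    px <- hdr$cellsize
  } else stop("malformed ASCII grid header (missing cellsize): ", path)
  if (!is.finite(px) || px <= 0) stop("invalid cellsize in ", path)
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) > nr * nc)
    stop("unsupported format (more values than one band holds): ", path)
  if (length(vals) < nr * nc)
    stop("truncated raster body: ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  crs <- "unspecified"
  sc <- crs_sidecar(path)
  if (file.exists(sc)) crs <- trimws(readLines(sc, n = 1L, warn = FALSE))
  grid_raster(m, origin_x = xll, origin_y = yll + nr * px,
              pixel_size = px, crs = crs, nodata = nodata)
}

#' Write a `grid_raster` as an ESRI ASCII grid
#'
#' Integer-valued rasters are written without a decimal point (exact
#' round-trip); continuous rasters use 17 significant digits so the round trip
#' is exact to double precision. The CRS label goes to a `.prj` sidecar.
#'
#' @param g A `grid_raster`.
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(g, path) {
  d <- dim(g$values)
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10f", g$origin_x),
    sprintf("yllcorner %.10f", g$origin_y - d[1] * g$pixel_size),
    sprintf("cellsize %.10f", g$pixel_size),
    sprintf("NODATA_value %s", format(g$nodata, scientific = FALSE))
  )
  all_int <- all(v == round(v) & abs(v) < 2^52)
  fmt <- if (all_int) "%.0f" else "%.17g"
  body <- apply(v, 1, function(r) paste(sprintf(fmt, r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  writeLines(g$crs, crs_sidecar(path))
  invisible(path)
}

#' Align a list of rasters onto a common grid
#'
#' All inputs must share a CRS. The output grid is the intersection of the
#' input extents at the finest input pixel size, anchored at the intersection's
#' north-west corner. Layers tagged `"categorical"` are resampled by nearest
#' neighbour, `"continuous"` layers bilinearly (with edge replication; a target
#' cell is `NA` when any of its contributing source cells is `NA`). Rasters
#' already on the common grid are passed through unchanged.
#'
#' @param rasters List of `grid_raster` objects.
#' @param tags Character vector, one of `"continuous"`/`"categorical"` per
#'   raster. Default: all continuous.
#' @return List of `grid_raster` objects on one identical grid.
#' @export
align_stack <- function(rasters, tags = rep("continuous", length(rasters))) {
  stopifnot(length(rasters) >= 1, length(tags) == length(rasters))
  if (!all(tags %in% c("continuous", "categorical")))
    stop("tags must be 'continuous' or 'categorical'")
  crs <- vapply(rasters, function(g) g$crs, "")
  if (length(unique(crs)) != 1)
    stop("CRS mismatch across rasters: ", paste(unique(crs), collapse = ", "))
  if (all(vapply(rasters, same_grid, TRUE, b = rasters[[1]])))
    return(rasters)
  exts <- vapply(rasters, grid_extent, numeric(4))
  xmin <- max(exts["xmin", ]); xmax <- min(exts["xmax", ])
  ymin <- max(exts["ymin", ]); ymax <- min(exts["ymax", ])
  px <- min(vapply(rasters, function(g) g$pixel_size, 0))
  nc <- floor((xmax - xmin) / px + 1e-9)
  nr <- floor((ymax - ymin) / px + 1e-9)
  if (nc < 1 || nr < 1)
    stop("empty intersection: raster extents do not overlap")
  tmpl <- list(origin_x = xmin, origin_y = ymax, pixel_size = px,
               nrow = nr, ncol = nc, crs = rasters[[1]]$crs)
  Map(function(g, tag) resample_to(g, tmpl, method = if (tag == "categorical") "nearest" else "bilinear"),
      rasters, tags)
}

# resample one raster onto a template geometry
resample_to <- function(g, tmpl, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  d <- dim(g$values)
  cx <- tmpl$origin_x + (seq_len(tmpl$ncol) - 0.5) * tmpl$pixel_size
  cy <- tmpl$origin_y - (seq_len(tmpl$nrow) - 0.5) * tmpl$pixel_size
  if (method == "nearest") {
    col <- pmin(pmax(floor((cx - g$origin_x) / g$pixel_size) + 1L, 1L), d[2])
    row <- pmin(pmax(floor((g$origin_y - cy) / g$pixel_size) + 1L, 1L), d[1])
    out <- g$values[row, col, drop = FALSE]
  } else {
    # fractional position of target centres on the source centre lattice
    gx <- (cx - (g$origin_x + 0.5 * g$pixel_size)) / g$pixel_size
    gy <- ((g$origin_y - 0.5 * g$pixel_size) - cy) / g$pixel_size
    c0 <- pmin(pmax(floor(gx) + 1L, 1L), d[2]); c1 <- pmin(c0 + 1L, d[2])
    r0 <- pmin(pmax(floor(gy) + 1L, 1L), d[1]); r1 <- pmin(r0 + 1L, d[1])
    fx <- pmin(pmax(gx - (c0 - 1L), 0), 1)
    fy <- pmin(pmax(gy - (r0 - 1L), 0), 1)
    wx0 <- matrix(1 - fx, tmpl$nrow, tmpl$ncol, byrow = TRUE)
    wy0 <- matrix(1 - fy, tmpl$nrow, tmpl$ncol)
    out <- g$values[r0, c0, drop = FALSE] * wy0 * wx0 +
      g$values[r0, c1, drop = FALSE] * wy0 * (1 - wx0) +
      g$values[r1, c0, drop = FALSE] * (1 - wy0) * wx0 +
      g$values[r1, c1, drop = FALSE] * (1 - wy0) * (1 - wx0)
  }
  grid_raster(out, tmpl$origin_x, tmpl$origin_y, tmpl$pixel_size,
              crs = tmpl$crs, nodata = g$nodata)
}

#' Rasterize a polygon set to a zone-id raster
#'
#' Each pixel receives the id of the polygon containing its centre; a centre
#' lying on a shared boundary is broken towards the lowest unit id; pixels in
#' no polygon are `NA`. Deterministic: identical inputs give identical outputs.
#'
#' @param polys A [polygon_set()].
#' @param template A `grid_raster` defining the output grid.
#' @return A `grid_raster` of integer unit ids (`NA` outside all polygons).
#' @export
rasterize_zones <- function(polys, template) {
  stopifnot(inherits(polys, "polygon_set"), inherits(template, "grid_raster"))
  if (length(polys$ids) == 0) stop("empty polygon set")
  d <- dim(template$values)
  cc <- cell_centers(template)
  X <- matrix(cc$x, d[1], d[2], byrow = TRUE)
  Y <- matrix(cc$y, d[1], d[2])
  out <- matrix(NA_real_, d[1], d[2])
  for (k in order(polys$ids)) {
    xy <- polys$polygons[[k]]
    bb <- poly_bbox(xy)
    cand <- which(is.na(out) & X >= bb[1] & X <= bb[2] & Y >= bb[3] & Y <= bb[4])
    if (length(cand) == 0) next
    hit <- point_in_poly(X[cand], Y[cand], xy)
    out[cand[hit]] <- polys$ids[k]
  }
  grid_raster(out, template$origin_x, template$origin_y, template$pixel_size,
              crs = template$crs, nodata = template$nodata)
}
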