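#' Polygon set on the working projection
#'
#' Plain container for zone / census-unit geometry: integer unit ids, one outer
#' ring per unit (2-column coordinate matrix, not closed), and optional
#' per-unit attributes. Rings are normalised to counter-clockwise orientation;
#' duplicated closing vertices are dropped. Interior rings (holes) are out of
#' scope.
#'
#' @param ids Integer vector of unique unit ids (>= 1).
#' @param polygons List of 2-column numeric matrices (x, y vertices).
#' @param attrs Optional data.frame of per-unit attributes (one row per id).
#' @param crs CRS label shared by all rings.
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(ids, polygons, attrs = NULL, crs = "local-m") {
  ids <- as.integer(ids)
  if (length(ids) != length(polygons)) stop("ids and polygons lengths differ")
  if (anyDuplicated(ids)) stop("unit ids must be unique")
  if (any(ids < 1)) stop("unit ids must be >= 1")
  polygons <- lapply(polygons, function(xy) {
    xy <- as.matrix(xy)
    if (ncol(xy) != 2) stop("each polygon must be a 2-column matrix")
    xy <- drop_closing_vertex(xy)
    if (nrow(xy) < 3) stop("polygon with fewer than 3 distinct vertices")
    if (poly_area(xy) <= 0) stop("polygon with zero area")
    ensure_ccw(xy)
  })
  if (!is.null(attrs) && nrow(attrs) != length(ids))
    stop("attrs must have one row per unit")
  structure(list(ids = ids, polygons = polygons, attrs = attrs, crs = crs),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d units, crs '%s'\n", length(x$ids), x$crs))
  invisible(x)
}

#' @export
length.polygon_set <- function(x) length(x$ids)

drop_closing_vertex <- function(xy) {
  n <- nrow(xy)
  while (n > 1 && all(xy[n, ] == xy[1, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1 }
  xy
}

signed_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  0.5 * sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])
}

#' Polygon area (shoelace formula)
#' @param xy 2-column vertex matrix.
#' @export
poly_area <- function(xy) abs(signed_area(xy))

ensure_ccw <- function(xy) if (signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy

poly_bbox <- function(xy) c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))

bbox_disjoint <- function(a, b) a[2] < b[1] || b[2] < a[1] || a[4] < b[3] || b[4] < a[3]

#' Point-in-polygon test (boundary inclusive)
#'
#' Vectorised ray casting over the query points, with an explicit on-segment
#' test so centres on an edge count as inside (ties across polygons are broken
#' elsewhere by lowest unit id).
#'
#' @param xs,ys Coordinates of query points.
#' @param xy Polygon ring (2-column matrix).
#' @param eps Boundary tolerance; default 1e-9 of the ring's bounding-box span.
#' @return Logical vector.
#' @export
point_in_poly <- function(xs, ys, xy, eps = NULL) {
  n <- nrow(xy)
  if (is.null(eps)) {
    bb <- poly_bbox(xy)
    eps <- 1e-9 * max(bb[2] - bb[1], bb[4] - bb[3], 1)
  }
  inside <- rep(FALSE, length(xs))
  onedge <- rep(FALSE, length(xs))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    if (yi != yj) {
      cross <- ((yi > ys) != (yj > ys)) &
        (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(pmax(((xs - xi) * dx + (ys - yi) * dy) / len2, 0), 1)
      d2 <- (xi + t * dx - xs)^2 + (yi + t * dy - ys)^2
      onedge <- onedge | d2 <= eps * eps
    }
    j <- i
  }
  inside | onedge
}

# keep the part of ring xy with nx*x + ny*y <= cc (one Sutherland-Hodgman step)
clip_halfplane <- function(xy, nx, ny, cc) {
  n <- nrow(xy)
  if (n == 0) return(xy)
  d <- xy[, 1] * nx + xy[, 2] * ny - cc
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) { keep_x <- c(keep_x, xy[i, 1]); keep_y <- c(keep_y, xy[i, 2]) }
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      keep_x <- c(keep_x, xy[i, 1] + t * (xy[j, 1] - xy[i, 1]))
      keep_y <- c(keep_y, xy[i, 2] + t * (xy[j, 2] - xy[i, 2]))
    }
  }
  cbind(keep_x, keep_y, deparse.level = 0)
}

# clip an arbitrary subject ring against a convex CCW clip ring
clip_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0) break
    j <- if (i == n) 1L else i + 1L
    ax <- clip[i, 1]; ay <- clip[i, 2]
    ex <- clip[j, 1] - ax; ey <- clip[j, 2] - ay
    # interior of a CCW ring is the left side of each edge
    out <- clip_halfplane(out, ey, -ex, ey * ax - ex * ay)
  }
  out
}

is_convex <- function(xy, eps = NULL) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  if (is.null(eps)) {
    bb <- poly_bbox(xy)
    eps <- 1e-12 * max(bb[2] - bb[1], bb[4] - bb[3], 1)^2
  }
  i0 <- seq_len(n); i1 <- c(2:n, 1); i2 <- c(3:n, 1, 2)
  cr <- (xy[i1, 1] - xy[i0, 1]) * (xy[i2, 2] - xy[i1, 2]) -
    (xy[i1, 2] - xy[i0, 2]) * (xy[i2, 1] - xy[i1, 1])
  all(cr >= -eps)
}

cross3 <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])

#' Triangulate a simple polygon by ear clipping
#'
#' @param xy CCW ring of a simple (non-self-intersecting) polygon.
#' @return List of 3x2 triangle matrices whose areas sum to the polygon area.
#' @export
triangulate_simple <- function(xy) {
  xy <- ensure_ccw(drop_closing_vertex(as.matrix(xy)))
  n <- nrow(xy)
  if (n < 3) stop("polygon with fewer than 3 vertices")
  if (n == 3) return(list(xy))
  bb <- poly_bbox(xy)
  eps <- 1e-12 * max(bb[2] - bb[1], bb[4] - bb[3], 1)^2
  idx <- seq_len(n)
  tris <- vector("list", n - 2); nt <- 0
  while (length(idx) > 3) {
    m <- length(idx); found <- FALSE
    for (k in seq_len(m)) {
      a <- idx[if (k == 1) m else k - 1]; b <- idx[k]; c <- idx[if (k == m) 1 else k + 1]
      if (cross3(xy[a, ], xy[b, ], xy[c, ]) <= eps) next   # reflex or degenerate corner
      others <- idx[!idx %in% c(a, b, c)]
      if (length(others) > 0) {
        px <- xy[others, 1]; py <- xy[others, 2]
        s1 <- (xy[b, 1] - xy[a, 1]) * (py - xy[a, 2]) - (xy[b, 2] - xy[a, 2]) * (px - xy[a, 1])
        s2 <- (xy[c, 1] - xy[b, 1]) * (py - xy[b, 2]) - (xy[c, 2] - xy[b, 2]) * (px - xy[b, 1])
        s3 <- (xy[a, 1] - xy[c, 1]) * (py - xy[c, 2]) - (xy[a, 2] - xy[c, 2]) * (px - xy[c, 1])
        # inclusive test: a vertex on the ear's boundary also blocks it,
        # otherwise clipping an ear grazed by a reflex corner double-counts
        if (any(s1 >= -eps & s2 >= -eps & s3 >= -eps)) next
      }
      nt <- nt + 1; tris[[nt]] <- xy[c(a, b, c), , drop = FALSE]
      idx <- idx[-k]; found <- TRUE
      break
    }
    if (!found) {
      # numerically degenerate ring: clip the most convex corner and continue
      m <- length(idx)
      crs <- vapply(seq_len(m), function(k) {
        cross3(xy[idx[if (k == 1) m else k - 1], ], xy[idx[k], ],
               xy[idx[if (k == m) 1 else k + 1], ])
      }, 0)
      k <- which.max(crs)
      a <- idx[if (k == 1) m else k - 1]; b <- idx[k]; c <- idx[if (k == m) 1 else k + 1]
      nt <- nt + 1; tris[[nt]] <- xy[c(a, b, c), , drop = FALSE]
      idx <- idx[-k]
    }
  }
  nt <- nt + 1; tris[[nt]] <- xy[idx, , drop = FALSE]
  tris[seq_len(nt)]
}

#' Intersection area of two simple polygons
#'
#' Convex rings are clipped directly (Sutherland-Hodgman); non-convex rings are
#' ear-clipped into triangles first and the pairwise triangle intersection
#' areas summed, which is exact for simple polygons.
#'
#' @param a,b 2-column vertex matrices.
#' @return Intersection area (>= 0).
#' @export
poly_intersection_area <- function(a, b) {
  a <- ensure_ccw(drop_closing_vertex(as.matrix(a)))
  b <- ensure_ccw(drop_closing_vertex(as.matrix(b)))
  if (bbox_disjoint(poly_bbox(a), poly_bbox(b))) return(0)
  ta <- if (is_convex(a)) list(a) else triangulate_simple(a)
  tb <- if (is_convex(b)) list(b) else triangulate_simple(b)
  total <- 0
  for (pa in ta) {
    bba <- poly_bbox(pa)
    for (pb in tb) {
      if (bbox_disjoint(bba, poly_bbox(pb))) next
      total <- total + poly_area(clip_convex(pa, pb))
    }
  }
  total
}

#' Voronoi tessellation of a convex boundary
#'
#' Builds the Voronoi cell of each generating centre by successive half-plane
#' clipping of the boundary ring against the perpendicular bisectors to every
#' other centre. The cells are convex and partition the boundary exactly; cell
#' `i` is the locus of points nearer centre `i` than any other, which matches
#' nearest-centre pixel assignment up to boundary ties.
#'
#' @param centers k x 2 matrix of generating points (inside the boundary).
#' @param boundary Convex ring (2-column matrix), e.g. the study rectangle.
#' @return List of k convex CCW rings.
#' @export
voronoi_polys <- function(centers, boundary) {
  centers <- as.matrix(centers)
  boundary <- ensure_ccw(drop_closing_vertex(as.matrix(boundary)))
  if (!is_convex(boundary)) stop("boundary must be convex")
  k <- nrow(centers)
  lapply(seq_len(k), function(i) {
    cell <- boundary
    ci <- centers[i, ]
    for (j in seq_len(k)) {
      if (j == i || nrow(cell) < 3) next
      cj <- centers[j, ]
      nx <- cj[1] - ci[1]; ny <- cj[2] - ci[2]
      if (nx == 0 && ny == 0) stop("duplicate Voronoi centres")
      mid <- (ci + cj) / 2
      cell <- clip_halfplane(cell, nx, ny, nx * mid[1] + ny * mid[2])
    }
    if (nrow(cell) < 3) stop("degenerate Voronoi cell for centre ", i)
    cell
  })
}

rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Read a polygon set from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features; only the outer ring of each
#' polygon is used. The unit id is taken from the named property (default
#' `unit_id`); all other properties become the attribute table.
#'
#' @param path GeoJSON file.
#' @param id_property Name of the feature property holding the unit id.
#' @param crs CRS label to attach (GeoJSON itself carries none here).
#' @return A [polygon_set()].
#' @export
read_polygons_geojson <- function(path, id_property = "unit_id", crs = "local-m") {
  stop_if_missing_file(path, "GeoJSON")
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a FeatureCollection: ", path)
  feats <- gj$features
  if (length(feats) == 0) stop("empty FeatureCollection: ", path)
  ids <- integer(length(feats))
  polys <- vector("list", length(feats))
  attr_rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      stop("unsupported geometry type '", f$geometry$type, "' in ", path)
    ring <- f$geometry$coordinates[[1]]
    polys[[i]] <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature ", i, " lacks property '", id_property, "'")
    ids[i] <- as.integer(id)
    props <- f$properties[setdiff(names(f$properties), id_property)]
    attr_rows[[i]] <- props
  }
  attrs <- NULL
  if (any(lengths(attr_rows) > 0)) {
    nm <- unique(unlist(lapply(attr_rows, names)))
    attrs <- as.data.frame(lapply(nm, function(k) {
      vapply(attr_rows, function(r) {
        v <- r[[k]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, 0)
    }), col.names = nm)
    names(attrs) <- nm
  }
  polygon_set(ids, polys, attrs = attrs, crs = crs)
}

#' Write a polygon set to GeoJSON
#'
#' @param ps A [polygon_set()].
#' @param path Output file.
#' @param id_property Property name for the unit id.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(ps, path, id_property = "unit_id") {
  feats <- lapply(seq_along(ps$ids), function(i) {
    xy <- ps$polygons[[i]]
    ring <- lapply(seq_len(nrow(xy) + 1), function(k) {
      k <- if (k > nrow(xy)) 1L else k
      c(xy[k, 1], xy[k, 2])
    })
    props <- stats::setNames(list(jsonlite::unbox(ps$ids[i])), id_property)
    if (!is.null(ps$attrs))
      for (nm in names(ps$attrs)) props[[nm]] <- jsonlite::unbox(ps$attrs[i, nm])
    list(type = jsonlite::unbox("Feature"),
         properties = props,
         geometry = list(type = jsonlite::unbox("Polygon"),
                         coordinates = list(ring)))
  })
  obj <- list(type = jsonlite::unbox("FeatureCollection"), features = feats)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
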