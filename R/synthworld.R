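#' Configuration of the synthetic multi-year world
#'
#' Defines a self-contained study area with the statistical structure the
#' density model assumes: growing built extents, lights correlated with built
#' area, smooth terrain, rivers, nested coarse (model) and fine (validation)
#' census tessellations, and per-pixel population drawn from a known density
#' law so census counts aggregate exactly.
#'
#' The density law at a pixel is
#' `log lambda = alpha - beta_t * d/1000 + gamma * L/lights_gain + eps`,
#' with `d` the signed distance to the built edge in metres (negative inside
#' built areas), `L` the noise-free expected lights brightness, and
#' `eps ~ N(0, sigma)` i.i.d. per pixel and year. In the `"static"` regime
#' `beta_t` is constant over years; in `"timevary"` it follows
#' `beta_by_year`, the world in which a single pooled model is structurally
#' wrong and per-year fitting pays off.
#'
#' @param nrow,ncol Grid size in pixels.
#' @param pixel_size Pixel side in metres.
#' @param years Ordered year labels.
#' @param n_coarse,n_fine Number of model-scale and validation-scale zones
#'   (fine zones nest exactly inside coarse zones; `n_fine >= n_coarse`).
#' @param n_blobs Number of built seed blobs.
#' @param blob_radius Built radius (m) around the seeds in the first year.
#' @param growth_radius Radial built growth (m) per subsequent year.
#' @param alpha Baseline log density (log people per pixel).
#' @param beta Distance-decay rate per km of built-edge distance ("static").
#' @param beta_by_year Per-year decay rates for the `"timevary"` regime.
#' @param gamma Coefficient on scaled lights.
#' @param sigma SD of the pixel-level log-density noise.
#' @param sigma_zone SD of a per-coarse-zone log-density random effect drawn
#'   independently per year: unobserved unit-level heterogeneity (local
#'   economy, housing stock) that no covariate carries. It bounds the
#'   achievable unit-level variance explained, and — because census counts
#'   carry it — it is exactly the component that dasymetric redistribution
#'   recovers at the pixel level.
#' @param lights_gain Peak expected brightness over fully built
#'   neighbourhoods (digital-number scale, clamped to [0, 63]).
#' @param lights_noise SD of the per-satellite brightness noise.
#' @param lights_radius_px Neighbourhood radius (pixels) of the built-fraction
#'   smoothing that drives lights.
#' @param terrain_smooth_px Gaussian smoothing radius (pixels) of the terrain
#'   field.
#' @param n_rivers Number of river polylines.
#' @param regime `"static"` or `"timevary"`.
#' @param seed RNG seed; the whole world is deterministic given it.
#' @return List of class `world_config`.
#' @export
world_config <- function(nrow = 200, ncol = 200, pixel_size = 100,
                         years = c(1990, 2000, 2010),
                         n_coarse = 100, n_fine = 400,
                         n_blobs = 12, blob_radius = 500, growth_radius = 400,
                         alpha = 2.0, beta = 1.0,
                         beta_by_year = c(0.4, 1.0, 2.2),
                         gamma = 1.0, sigma = 0.2, sigma_zone = 0.55,
                         lights_gain = 40, lights_noise = 2,
                         lights_radius_px = 5, terrain_smooth_px = 8,
                         n_rivers = 3,
                         regime = c("static", "timevary"), seed = 20160205) {
  regime <- match.arg(regime)
  if (length(years) < 1) stop("at least one year required")
  if (n_fine < n_coarse) stop("n_fine must be >= n_coarse")
  if (any(c(nrow, ncol, pixel_size, n_coarse, n_fine, n_blobs,
            blob_radius, growth_radius, sigma, lights_gain) <= 0) &&
      sigma < 0)
    stop("world parameters must be positive where applicable")
  if (regime == "timevary" && length(beta_by_year) != length(years))
    stop("beta_by_year must have one rate per year")
  structure(list(nrow = nrow, ncol = ncol, pixel_size = pixel_size,
                 years = years, n_coarse = n_coarse, n_fine = n_fine,
                 n_blobs = n_blobs, blob_radius = blob_radius,
                 growth_radius = growth_radius, alpha = alpha, beta = beta,
                 beta_by_year = beta_by_year, gamma = gamma, sigma = sigma,
                 sigma_zone = sigma_zone,
                 lights_gain = lights_gain, lights_noise = lights_noise,
                 lights_radius_px = lights_radius_px,
                 terrain_smooth_px = terrain_smooth_px, n_rivers = n_rivers,
                 regime = regime, seed = seed),
            class = "world_config")
}

# separable Gaussian smoothing with edge replication
gaussian_smooth <- function(m, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

# mean of a binary mask within a square neighbourhood of half-width r pixels
box_fraction <- function(mask, r) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

# nearest-centre assignment of points to k centres (squared Euclidean)
nearest_center <- function(pts, centers) {
  d2 <- outer(rowSums(pts^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(pts)), rowSums(centers^2)) - 2 * pts %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Generate a synthetic multi-year world
#'
#' Realises a [world_config()]: smoothed random terrain; monotone random-walk
#' rivers; built extents grown by per-year dilation of seed blobs (cellwise
#' non-decreasing over years by construction); per-satellite lights as a gain
#' on the local built fraction plus noise (the middle year gets two satellite
#' rasters, to be composited downstream); per-pixel true population from the
#' configured density law, rescaled so every coarse-zone total is an integer;
#' and coarse/fine census tables as exact zonal sums. Coarse zones are the
#' Voronoi tessellation of k-means centres on the pixel lattice; fine zones
#' are Voronoi tessellations nested exactly inside each coarse cell.
#' Bit-identical given the same config (the seed covers every draw).
#'
#' @param cfg A [world_config()].
#' @return List of class `synthetic_world`; see the fields in the source.
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  set.seed(cfg$seed)
  nr <- cfg$nrow; nc <- cfg$ncol; px <- cfg$pixel_size
  ny <- length(cfg$years)
  gr <- function(values) grid_raster(values, origin_x = 0, origin_y = nr * px,
                                     pixel_size = px, crs = "local-m")

  # terrain: smoothed Gaussian field, rescaled to 0..500 m
  z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), cfg$terrain_smooth_px)
  z <- (z - min(z)) / (max(z) - min(z)) * 500
  elevation <- gr(z)

  # rivers: west-to-east monotone random walks
  riv <- matrix(0, nr, nc)
  for (k in seq_len(cfg$n_rivers)) {
    r <- sample.int(nr, 1)
    for (cix in seq_len(nc)) {
      riv[r, cix] <- 1
      r <- min(max(r + sample(c(-1L, 0L, 1L), 1), 1L), nr)
    }
  }
  rivers <- gr(riv)

  # built extents: blobs dilated per year; regenerate smaller if they flood the grid
  radii <- cfg$blob_radius + (seq_len(ny) - 1) * cfg$growth_radius
  repeat {
    seeds <- matrix(0, nr, nc)
    seeds[cbind(sample.int(nr, cfg$n_blobs, replace = TRUE),
                sample.int(nc, cfg$n_blobs, replace = TRUE))] <- 1
    dseed <- .edt(seeds == 1, px)
    built_frac_last <- mean(dseed <= radii[ny])
    if (built_frac_last < 0.5 && built_frac_last > 0) break
    radii <- radii * 0.8
    dp_log("generate_world: built blobs exceeded grid; shrinking radii")
  }
  built <- lapply(radii, function(r) gr(matrix(as.numeric(dseed <= r), nr, nc)))

  # lights: gain on local built fraction; per-satellite observation noise;
  # the middle year carries two satellites when there are >= 3 years
  lights_true <- lapply(built, function(b)
    pmin(cfg$lights_gain * box_fraction(b$values == 1, cfg$lights_radius_px),
         63))
  two_sat_year <- if (ny >= 3) 2L else 0L
  lights <- lapply(seq_len(ny), function(t) {
    n_sat <- if (t == two_sat_year) 2L else 1L
    obs <- lapply(seq_len(n_sat), function(s)
      gr(pmin(pmax(lights_true[[t]] +
                     matrix(stats::rnorm(nr * nc, 0, cfg$lights_noise), nr, nc),
                   0), 63)))
    if (n_sat == 1) obs[[1]] else obs
  })

  # density law and true population
  betas <- if (cfg$regime == "static") rep(cfg$beta, ny) else cfg$beta_by_year
  dists <- lapply(built, function(b) signed_distance_to_edge(b)$values)
  lam <- lapply(seq_len(ny), function(t) {
    eps <- matrix(stats::rnorm(nr * nc, 0, cfg$sigma), nr, nc)
    exp(cfg$alpha - betas[t] * dists[[t]] / 1000 +
          cfg$gamma * lights_true[[t]] / cfg$lights_gain + eps)
  })

  # census tessellations: k-means coarse zones, fine zones nested inside them
  cc <- cell_centers(elevation)
  pts <- cbind(rep(cc$x, each = nr), rep(cc$y, times = nc))
  km <- suppressWarnings(stats::kmeans(pts, centers = cfg$n_coarse,
                                       iter.max = 50, algorithm = "Lloyd"))
  ccent <- unname(km$centers)
  coarse_assign <- nearest_center(pts, ccent)
  boundary <- rect_ring(0, nc * px, 0, nr * px)
  coarse_rings <- voronoi_polys(ccent, boundary)
  coarse_polys <- polygon_set(seq_len(cfg$n_coarse), coarse_rings, crs = "local-m")

  npix_coarse <- tabulate(coarse_assign, cfg$n_coarse)
  k_fine <- largest_remainder(cfg$n_fine, npix_coarse)
  fine_assign <- integer(nr * nc)
  fine_rings <- vector("list", cfg$n_fine)
  fine_parent <- integer(cfg$n_fine)
  nxt <- 0L
  for (i in seq_len(cfg$n_coarse)) {
    in_i <- which(coarse_assign == i)
    ki <- k_fine[i]
    if (ki == 1) {
      nxt <- nxt + 1L
      fine_assign[in_i] <- nxt
      fine_rings[[nxt]] <- coarse_rings[[i]]
      fine_parent[nxt] <- i
      next
    }
    kmi <- suppressWarnings(stats::kmeans(pts[in_i, , drop = FALSE], centers = ki,
                                          iter.max = 50, algorithm = "Lloyd"))
    fcent <- unname(kmi$centers)
    sub <- nearest_center(pts[in_i, , drop = FALSE], fcent)
    cells <- voronoi_polys(fcent, coarse_rings[[i]])
    for (j in seq_len(ki)) {
      nxt <- nxt + 1L
      fine_assign[in_i[sub == j]] <- nxt
      fine_rings[[nxt]] <- cells[[j]]
      fine_parent[nxt] <- i
    }
  }
  fine_polys <- polygon_set(seq_len(cfg$n_fine), fine_rings,
                            attrs = data.frame(coarse_id = fine_parent),
                            crs = "local-m")
  coarse_zones <- gr(matrix(as.numeric(coarse_assign), nr, nc))
  fine_zones <- gr(matrix(as.numeric(fine_assign), nr, nc))

  # scale true density so each coarse-zone total is an integer count
  cz <- factor(coarse_assign, levels = seq_len(cfg$n_coarse))
  fz <- factor(fine_assign, levels = seq_len(cfg$n_fine))
  ppp_true <- vector("list", ny)
  census_coarse <- NULL; census_fine <- NULL
  for (t in seq_len(ny)) {
    # unobserved per-zone heterogeneity, redrawn each year
    zeta <- exp(stats::rnorm(cfg$n_coarse, 0, cfg$sigma_zone))
    lam_t <- as.numeric(lam[[t]]) * zeta[coarse_assign]
    s <- as.numeric(rowsum(lam_t, cz))
    target <- pmax(1, round(s))
    f <- target / s
    v <- matrix(lam_t * f[coarse_assign], nr, nc)
    ppp_true[[t]] <- gr(v)
    census_coarse <- rbind(census_coarse,
                           data.frame(unit_id = seq_len(cfg$n_coarse),
                                      population = target,
                                      year = cfg$years[t]))
    census_fine <- rbind(census_fine,
                         data.frame(unit_id = seq_len(cfg$n_fine),
                                    population = as.numeric(rowsum(as.numeric(v), fz)),
                                    year = cfg$years[t]))
  }

  structure(list(config = cfg, elevation = elevation, rivers = rivers,
                 built = built, lights = lights, ppp_true = ppp_true,
                 coarse_polys = coarse_polys, fine_polys = fine_polys,
                 coarse_zones = coarse_zones, fine_zones = fine_zones,
                 census_coarse = census_coarse, census_fine = census_fine),
            class = "synthetic_world")
}

# integer apportionment of k among groups proportional to sizes, each >= 1
largest_remainder <- function(k, sizes) {
  q <- k * sizes / sum(sizes)
  base <- pmax(1L, floor(q))
  d <- k - sum(base)
  if (d > 0) {
    o <- order(q - floor(q), decreasing = TRUE)
    base[o[seq_len(d)]] <- base[o[seq_len(d)]] + 1L
  } else if (d < 0) {
    o <- order(q - floor(q))
    take <- o[base[o] > 1][seq_len(-d)]
    base[take] <- base[take] - 1L
  }
  base
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<synthetic_world> %dx%d @ %g m, years %s, %d coarse / %d fine zones (%s)\n",
              cfg$nrow, cfg$ncol, cfg$pixel_size,
              paste(cfg$years, collapse = "/"),
              cfg$n_coarse, cfg$n_fine, cfg$regime))
  invisible(x)
}

#' Write a synthetic world as pipeline input fixtures
#'
#' Emits every raster (`.asc`), zone set (GeoJSON and zone-id raster), census
#' table (CSV) and a JSON manifest into `out_dir`, in exactly the formats the
#' pipeline stages consume, so a run needs no inputs beyond this directory.
#'
#' @param world A [generate_world()] result.
#' @param out_dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
emit_fixtures <- function(world, out_dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- world$config
  files <- list()
  wr <- function(g, name) {
    p <- file.path(out_dir, paste0(name, ".asc"))
    write_raster(g, p)
    p
  }
  files$elevation <- wr(world$elevation, "elevation")
  files$rivers <- wr(world$rivers, "rivers")
  files$built <- character(0)
  files$lights <- list()
  files$ppp_true <- character(0)
  for (t in seq_along(cfg$years)) {
    y <- cfg$years[t]
    files$built[as.character(y)] <- wr(world$built[[t]], paste0("built_", y))
    li <- world$lights[[t]]
    files$lights[[as.character(y)]] <-
      if (inherits(li, "grid_raster")) wr(li, paste0("lights_", y))
      else vapply(seq_along(li), function(s)
        wr(li[[s]], sprintf("lights_%s_sat%d", y, s)), "")
    files$ppp_true[as.character(y)] <- wr(world$ppp_true[[t]], paste0("ppp_true_", y))
  }
  files$coarse_zones_geojson <- file.path(out_dir, "coarse_zones.geojson")
  write_polygons_geojson(world$coarse_polys, files$coarse_zones_geojson)
  files$fine_zones_geojson <- file.path(out_dir, "fine_zones.geojson")
  write_polygons_geojson(world$fine_polys, files$fine_zones_geojson)
  files$coarse_zones <- wr(world$coarse_zones, "coarse_zones")
  files$fine_zones <- wr(world$fine_zones, "fine_zones")
  files$census_coarse <- file.path(out_dir, "census_coarse.csv")
  write_census_csv(world$census_coarse, files$census_coarse)
  files$census_fine <- file.path(out_dir, "census_fine.csv")
  write_census_csv(world$census_fine, files$census_fine)

  totals <- vapply(split(world$census_coarse$population, world$census_coarse$year),
                   sum, 0)
  manifest <- list(
    config = unclass(cfg), seed = cfg$seed, years = cfg$years,
    files = files, total_population = as.list(totals)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
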