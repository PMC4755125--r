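# Independent oracles and shared fixtures, built in code.

# O(pixels x features) all-pairs nearest-feature distance (metres)
brute_edt <- function(mask, px) {
  nr <- nrow(mask); nc <- ncol(mask)
  fr <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- sqrt(min((r - fr[, 1])^2 + (c - fr[, 2])^2)) * px
  out
}

# brute-force signed distance: positive outside built, negative inside
brute_signed <- function(built, px) {
  d_b <- brute_edt(built == 1, px)
  d_o <- brute_edt(built == 0, px)
  ifelse(built == 1, -d_o, d_b)
}

# irregular but evenly-sized random tessellation: Voronoi of k-means centres
# (the same construction the synthetic world uses for its census zones)
kmeans_tessellation <- function(k, ext, npts = 3000) {
  pts <- cbind(stats::runif(npts, 0, ext), stats::runif(npts, 0, ext))
  cent <- unname(suppressWarnings(
    stats::kmeans(pts, k, iter.max = 50, algorithm = "Lloyd"))$centers)
  polygon_set(seq_len(k), voronoi_polys(cent, dasypop:::rect_ring(0, ext, 0, ext)))
}

# small world for unit tests, generated once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_world <- function() cached("small_world", generate_world(small_world_config()))

small_world_config <- function(...) {
  world_config(nrow = 80, ncol = 80, n_coarse = 25, n_fine = 75,
               n_blobs = 6, seed = 101, ...)
}

small_world_fit <- function(t = 1) {
  cached(paste0("small_fit_", t), {
    w <- small_world()
    stacks <- cached("small_stacks", world_stacks(w))
    cen <- world_harmonized(w, w$config$years[t])
    tab <- zonal_summarize(stacks[[t]], w$coarse_zones, cen)
    model <- fit_forest(tab, seed = 300 + t)
    list(world = w, stack = stacks[[t]], census = cen, table = tab,
         model = model,
         weights = predict_density_surface(model, stacks[[t]]))
  })
}
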