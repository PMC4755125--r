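px100 <- function(v) grid_raster(v, pixel_size = 100)

test_that("signed distance around a single built pixel matches adjacency geometry", {
  m <- matrix(0, 5, 5)
  m[3, 3] <- 1
  d <- signed_distance_to_edge(px100(m))
  expect_equal(d$values[3, 3], -100)            # built cell: -dist to nearest open
  expect_equal(d$values[2, 3], 100)             # 4-neighbours
  expect_equal(d$values[3, 4], 100)
  expect_equal(d$values[2, 2], 100 * sqrt(2))   # diagonal neighbour
  expect_equal(d$values[1, 1], 100 * sqrt(8))
})

test_that("signed distance sign partitions the mask and is never zero", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(as.numeric(stats::runif(400) < 0.3), 20, 20)
    if (!any(m == 1) || !any(m == 0)) next
    d <- signed_distance_to_edge(px100(m))
    expect_true(all(d$values[m == 1] < 0))
    expect_true(all(d$values[m == 0] > 0))
    expect_true(all(abs(d$values) >= 100))
  }
})

test_that("distance transforms match the all-pairs brute-force oracle", {
  set.seed(31)
  for (i in 1:10) {
    nr <- sample(20:30, 1); nc <- sample(20:30, 1)
    m <- matrix(as.numeric(stats::runif(nr * nc) < 0.15), nr, nc)
    if (!any(m == 1) || !any(m == 0)) next
    expect_equal(signed_distance_to_edge(px100(m))$values, brute_signed(m, 100))
    expect_equal(distance_to_features(px100(m))$values, brute_edt(m == 1, 100))
  }
})

test_that("distances are translation-invariant and scale with pixel size", {
  set.seed(8)
  m <- matrix(as.numeric(stats::runif(240) < 0.2), 12, 20)
  a <- signed_distance_to_edge(grid_raster(m, origin_x = 0, pixel_size = 100))
  b <- signed_distance_to_edge(grid_raster(m, origin_x = 5e5, pixel_size = 100))
  expect_identical(a$values, b$values)
  c2 <- signed_distance_to_edge(grid_raster(m, pixel_size = 200))
  expect_equal(c2$values, 2 * a$values)
})

test_that("distance transforms propagate NA and reject degenerate masks", {
  m <- matrix(c(1, 0, NA, 0), 2, 2)
  d <- signed_distance_to_edge(px100(m))
  expect_true(is.na(d$values[1, 2]))
  expect_equal(d$values[1, 1], -100)
  expect_error(signed_distance_to_edge(px100(matrix(1, 3, 3))), "all cells built")
  expect_error(signed_distance_to_edge(px100(matrix(0, 3, 3))), "no built cells")
  expect_error(distance_to_features(px100(matrix(0, 3, 3))), "no feature cells")
  expect_error(signed_distance_to_edge(px100(matrix(c(0, 2), 2, 2))), "only 0, 1, NA")
})

test_that("feature cells are at distance zero and collinear cells at pixel multiples", {
  m <- matrix(0, 1, 5)
  m[1, 1] <- 1
  d <- distance_to_features(px100(m))
  expect_equal(d$values[1, ], c(0, 100, 200, 300, 400))
})

test_that("Horn slope is zero on flat terrain and exact on an inclined plane", {
  flat <- px100(matrix(250, 6, 6))
  expect_true(all(slope_from_elevation(flat)$values == 0))
  # plane rising 10 m per 100 m eastwards
  plane <- px100(outer(rep(1, 8), (0:7) * 10))
  s <- slope_from_elevation(plane)
  expect_equal(s$values[3:6, 3:6],
               matrix(atan(0.1) * 180 / pi, 4, 4), tolerance = 1e-12)
  expect_error(slope_from_elevation(px100(matrix(0, 2, 5))), "at least 3x3")
})

test_that("slope of a symmetric cone is invariant under 90-degree rotation", {
  n <- 21
  r <- sqrt(outer((1:n - 11)^2, (1:n - 11)^2, `+`))
  cone <- px100(500 - 20 * r)
  s <- slope_from_elevation(cone)$values
  rot <- t(s[n:1, ])   # 90-degree rotation
  expect_equal(s, rot, tolerance = 1e-12)
})

test_that("lights compositing averages cellwise with strict NA propagation", {
  a <- px100(matrix(10, 3, 3))
  b <- px100(matrix(20, 3, 3))
  b$values[2, 2] <- NA
  expect_identical(composite_lights(list(a)), a)
  out <- composite_lights(list(a, b))
  expect_equal(out$values[1, 1], 15)
  expect_true(is.na(out$values[2, 2]))
  set.seed(2)
  rs <- lapply(1:3, function(i) px100(matrix(stats::runif(9), 3, 3)))
  comp <- composite_lights(rs)$values
  lo <- pmin(rs[[1]]$values, rs[[2]]$values, rs[[3]]$values)
  hi <- pmax(rs[[1]]$values, rs[[2]]$values, rs[[3]]$values)
  expect_true(all(comp >= lo & comp <= hi))
  shifted <- grid_raster(matrix(1, 3, 3), origin_x = 50, pixel_size = 100)
  expect_error(composite_lights(list(a, shifted)), "not grid-aligned")
})

test_that("build_stack applies the preceding-years built-distance rule", {
  w <- small_world()
  static <- list(elevation = w$elevation, rivers = w$rivers)
  s0 <- build_stack(0, w$config$years, static, w$lights, w$built)
  expect_named(s0$layers, c("lights", "elevation", "slope", "dist_water",
                            "built_dist_1990"))
  s2 <- build_stack(2, w$config$years, static, w$lights, w$built)
  expect_length(s2$layers, 7)
  expect_named(s2$layers, c("lights", "elevation", "slope", "dist_water",
                            "built_dist_1990", "built_dist_2000",
                            "built_dist_2010"))
  # determinism
  s2b <- build_stack(2, w$config$years, static, w$lights, w$built)
  expect_identical(lapply(s2$layers, `[[`, "values"),
                   lapply(s2b$layers, `[[`, "values"))
  expect_error(build_stack(2, w$config$years, static, w$lights, w$built[1:2]),
               "missing built mask")
  expect_error(build_stack(5, w$config$years, static, w$lights, w$built),
               "out of range")
})

test_that("stack write/read round-trips layers and year", {
  w <- small_world()
  s0 <- build_stack(0, w$config$years, list(elevation = w$elevation,
                                            rivers = w$rivers),
                    w$lights, w$built)
  d <- file.path(tempdir(), "stack_rt")
  write_stack(s0, d)
  s0b <- read_stack(d)
  expect_equal(s0b$year, s0$year)
  expect_named(s0b$layers, names(s0$layers))
  expect_equal(s0b$layers$built_dist_1990$values, s0$layers$built_dist_1990$values,
               tolerance = 1e-12)
})
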