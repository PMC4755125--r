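test_that("raster write/read round-trips values, transform and nodata", {
  v <- matrix(c(1, 2, 3, 4, NA, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  g <- grid_raster(v, origin_x = 1000, origin_y = 2300, pixel_size = 100,
                   crs = "local-m", nodata = -9999)
  p <- file.path(tempdir(), "rt_int.asc")
  write_raster(g, p)
  g2 <- read_raster(p)
  expect_identical(g2$values, g$values)
  expect_equal(g2$origin_x, g$origin_x)
  expect_equal(g2$origin_y, g$origin_y)
  expect_equal(g2$pixel_size, g$pixel_size)
  expect_identical(g2$crs, "local-m")
  expect_true(is.na(g2$values[2, 2]))  # sentinel -> NA

  vf <- matrix(stats::runif(12) * 1e3 + 0.123456789, 3, 4)
  gf <- grid_raster(vf, pixel_size = 50)
  pf <- file.path(tempdir(), "rt_float.asc")
  write_raster(gf, pf)
  expect_equal(read_raster(pf)$values, vf, tolerance = 1e-12)
})

test_that("non-square pixels and malformed bodies are rejected", {
  p <- file.path(tempdir(), "nonsquare.asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "dx 100", "dy 50", "NODATA_value -9999",
               "1 2", "3 4"), p)
  expect_error(read_raster(p), "non-square")

  p2 <- file.path(tempdir(), "overfull.asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 100", "NODATA_value -9999",
               "1 2", "3 4", "5 6"), p2)
  expect_error(read_raster(p2), "unsupported format")
  expect_error(read_raster(file.path(tempdir(), "missing.asc")), "not found")
})

test_that("align_stack passes identical grids through unchanged", {
  a <- grid_raster(matrix(1:9, 3, 3), pixel_size = 100)
  b <- grid_raster(matrix(9:1, 3, 3), pixel_size = 100)
  out <- align_stack(list(a, b))
  expect_identical(out[[1]], a)
  expect_identical(out[[2]], b)
})

test_that("align_stack duplicates coarse categorical cells into fine blocks", {
  coarse <- grid_raster(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE),
                        origin_x = 0, origin_y = 400, pixel_size = 200)
  fine <- grid_raster(matrix(0, 4, 4), origin_x = 0, origin_y = 400, pixel_size = 100)
  out <- align_stack(list(coarse, fine), c("categorical", "continuous"))
  expect_equal(dim(out[[1]]$values), c(4, 4))
  expect_equal(out[[1]]$values,
               matrix(c(1, 1, 2, 2,
                        1, 1, 2, 2,
                        3, 3, 4, 4,
                        3, 3, 4, 4), 4, 4, byrow = TRUE))
})

test_that("bilinear alignment of a half-pixel-shifted ramp averages straddled cells", {
  ramp <- matrix(rep(1:4, each = 4), 4, 4, byrow = FALSE)  # value = column index
  a <- grid_raster(ramp, origin_x = 0, origin_y = 400, pixel_size = 100)
  b <- grid_raster(matrix(0, 4, 4), origin_x = 50, origin_y = 400, pixel_size = 100)
  out <- align_stack(list(a, b), c("continuous", "continuous"))
  # target centres sit midway between source centres: exact two-cell means
  expect_equal(out[[1]]$values[1, ], c(1.5, 2.5, 3.5))
})

test_that("aligned rasters share shape, origin and pixel size exactly", {
  set.seed(4)
  a <- grid_raster(matrix(stats::runif(100), 10, 10), origin_x = 0,
                   origin_y = 1000, pixel_size = 100)
  b <- grid_raster(matrix(stats::runif(36), 6, 6), origin_x = 150,
                   origin_y = 950, pixel_size = 150)
  out <- align_stack(list(a, b))
  expect_identical(dim(out[[1]]$values), dim(out[[2]]$values))
  expect_identical(out[[1]]$origin_x, out[[2]]$origin_x)
  expect_identical(out[[1]]$origin_y, out[[2]]$origin_y)
  expect_identical(out[[1]]$pixel_size, out[[2]]$pixel_size)
})

test_that("align_stack rejects disjoint extents and CRS mismatches", {
  a <- grid_raster(matrix(0, 3, 3), origin_x = 0, origin_y = 300, pixel_size = 100)
  b <- grid_raster(matrix(0, 3, 3), origin_x = 5000, origin_y = 300, pixel_size = 100)
  expect_error(align_stack(list(a, b)), "empty intersection")
  d <- grid_raster(matrix(0, 3, 3), pixel_size = 100, crs = "other")
  expect_error(align_stack(list(a, d)), "CRS mismatch")
})

test_that("rasterize_zones covers full-extent and half-plane splits", {
  tmpl <- grid_raster(matrix(0, 4, 4), origin_x = 0, origin_y = 400, pixel_size = 100)
  all_cover <- polygon_set(7, list(dasypop:::rect_ring(-10, 410, -10, 410)))
  z <- rasterize_zones(all_cover, tmpl)
  expect_true(all(z$values == 7))

  halves <- polygon_set(1:2, list(dasypop:::rect_ring(0, 200, 0, 400),
                                  dasypop:::rect_ring(200, 400, 0, 400)))
  z2 <- rasterize_zones(halves, tmpl)
  expect_equal(sum(z2$values == 1), 8)
  expect_equal(sum(z2$values == 2), 8)
  expect_false(anyNA(z2$values))
})

test_that("rasterize_zones matches all-pixel point-in-polygon and is deterministic", {
  set.seed(42)
  ext <- 5000
  ps <- kmeans_tessellation(8, ext, npts = 800)
  tmpl <- grid_raster(matrix(0, 50, 50), origin_x = 0, origin_y = ext, pixel_size = 100)
  z <- rasterize_zones(ps, tmpl)
  cc <- cell_centers(tmpl)
  ref <- matrix(NA_real_, 50, 50)
  for (r in 1:50) for (c in 1:50) {
    for (k in order(ps$ids)) {
      if (point_in_poly(cc$x[c], cc$y[r], ps$polygons[[k]])) {
        ref[r, c] <- ps$ids[k]
        break
      }
    }
  }
  expect_identical(z$values, ref)
  expect_identical(rasterize_zones(ps, tmpl)$values, z$values)
  expect_error(rasterize_zones(polygon_set(integer(0), list()), tmpl))
})
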