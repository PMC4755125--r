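test_that("counts are spread proportionally to weights within a zone", {
  zones <- grid_raster(matrix(1, 1, 2), pixel_size = 100)
  weights <- grid_raster(matrix(c(1, 3), 1, 2), pixel_size = 100)
  ppp <- redistribute(harmonized_census(c(`1` = 100)), weights, zones)
  expect_equal(ppp$values, matrix(c(25, 75), 1, 2))
})

test_that("zero-weight zones fall back to uniform allocation", {
  zones <- grid_raster(matrix(1, 1, 5), pixel_size = 100)
  weights <- grid_raster(matrix(0, 1, 5), pixel_size = 100)
  expect_message(
    ppp <- redistribute(harmonized_census(c(`1` = 10)), weights, zones),
    "uniform fallback")
  expect_equal(ppp$values, matrix(2, 1, 5))
})

test_that("NA-weight pixels get zero people when the zone has usable weight", {
  zones <- grid_raster(matrix(1, 1, 3), pixel_size = 100)
  weights <- grid_raster(matrix(c(2, NA, 2), 1, 3), pixel_size = 100)
  ppp <- redistribute(harmonized_census(c(`1` = 10)), weights, zones)
  expect_equal(ppp$values, matrix(c(5, 0, 5), 1, 3))
})

test_that("redistribution conserves every zone total on the small world", {
  fit <- small_world_fit(1)
  ppp <- redistribute(fit$census, fit$weights, fit$world$coarse_zones)
  res <- conservation_residuals(ppp, fit$world$coarse_zones, fit$census)
  expect_lt(max(res), 1e-9)
  total <- sum(ppp$values, na.rm = TRUE)
  expect_equal(total, sum(fit$census$counts), tolerance = 1e-12)
})

test_that("redistribution is invariant to rescaling the weighting layer", {
  fit <- small_world_fit(1)
  ppp1 <- redistribute(fit$census, fit$weights, fit$world$coarse_zones)
  w2 <- dasypop:::with_values(fit$weights, fit$weights$values * 7.3)
  ppp2 <- redistribute(fit$census, w2, fit$world$coarse_zones)
  expect_equal(ppp1$values, ppp2$values, tolerance = 1e-12)
})

test_that("within a zone, more weight means more people", {
  zones <- grid_raster(matrix(1, 2, 3), pixel_size = 100)
  set.seed(6)
  wv <- matrix(stats::runif(6, 0.1, 5), 2, 3)
  weights <- grid_raster(wv, pixel_size = 100)
  ppp <- redistribute(harmonized_census(c(`1` = 50)), weights, zones)
  expect_equal(order(ppp$values), order(wv))
})

test_that("missing ids are handled on both sides", {
  zones <- grid_raster(matrix(c(1, 2), 2, 2), pixel_size = 100)
  weights <- grid_raster(matrix(1, 2, 2), pixel_size = 100)
  expect_error(redistribute(harmonized_census(c(`1` = 5)), weights, zones),
               "no census count for zone")
  ppp <- suppressMessages(
    redistribute(harmonized_census(c(`1` = 5, `2` = 5, `9` = 7)), weights, zones))
  expect_equal(as.numeric(attr(ppp, "undistributed")), 7)

  # pixels outside all zones stay NA
  zv <- matrix(c(1, NA, 1, NA), 2, 2)
  ppp2 <- redistribute(harmonized_census(c(`1` = 8)),
                       grid_raster(matrix(1, 2, 2), pixel_size = 100),
                       grid_raster(zv, pixel_size = 100))
  expect_equal(is.na(ppp2$values), is.na(zv))
  expect_equal(sum(ppp2$values, na.rm = TRUE), 8)
})

test_that("people per hectare scales by pixel area and conserves mass", {
  v <- matrix(c(1, 2, 3, 4), 2, 2)
  p100 <- grid_raster(v, pixel_size = 100)       # 1 ha pixels
  expect_equal(ppp_to_pph(p100)$values, v)
  p50 <- grid_raster(v, pixel_size = 50)         # 0.25 ha pixels
  expect_equal(ppp_to_pph(p50)$values, 4 * v)
  # pph x pixel area re-sums to the zone count
  area_ha <- p50$pixel_size^2 / 1e4
  expect_equal(sum(ppp_to_pph(p50)$values * area_ha), sum(v))
})

test_that("product export round-trips and identity reprojection reuses the grids", {
  fit <- small_world_fit(1)
  ppp <- redistribute(fit$census, fit$weights, fit$world$coarse_zones)
  out <- file.path(tempdir(), "products")
  rep1 <- export_products(ppp, out, iso = "SYN", year = 1990,
                          out_crs = ppp$crs)
  expect_identical(rep1$files$ppp_export, rep1$files$ppp)   # identity: same file
  back <- read_raster(rep1$files$ppp)
  expect_equal(back$values, ppp$values, tolerance = 1e-7)   # float32-level
  pph <- read_raster(rep1$files$pph)
  expect_equal(pph$values, ppp$values, tolerance = 1e-7)    # 100 m = 1 ha pixels
})

test_that("geographic export conserves the total within one percent", {
  fit <- small_world_fit(1)
  ppp <- redistribute(fit$census, fit$weights, fit$world$coarse_zones)
  out <- file.path(tempdir(), "products_wgs")
  rep2 <- export_products(ppp, out, iso = "SYN", year = 1990, out_crs = "wgs84")
  expect_lt(abs(rep2$report$export_total - rep2$report$working_total) /
              rep2$report$working_total, 0.01)
  g <- read_raster(rep2$files$ppp_export)
  expect_identical(g$crs, "wgs84")
})
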