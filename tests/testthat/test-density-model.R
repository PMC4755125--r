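make_toy_table <- function(n, f, sigma = 0, seed = 1, extra_noise_covs = 0) {
  set.seed(seed)
  x1 <- stats::runif(n, -2, 2)
  tab <- data.frame(zone_id = seq_len(n), pixel_count = 100L, area_ha = 100,
                    cov1 = x1)
  covs <- "cov1"
  if (extra_noise_covs > 0) {
    for (k in seq_len(extra_noise_covs)) {
      nm <- paste0("noise", k)
      tab[[nm]] <- stats::rnorm(n)
      covs <- c(covs, nm)
    }
  }
  tab$count <- 1
  tab$log_density <- f(x1) + stats::rnorm(n, 0, sigma)
  structure(tab, class = c("zonal_table", "data.frame"), covariates = covs)
}

test_that("zonal summaries compute exact means, pixel counts and log density", {
  # 4x4 grid: zone 1 = left half (8 px), zone 2 = right half
  zones <- grid_raster(matrix(rep(c(1, 1, 2, 2), 4), 4, 4, byrow = TRUE),
                       pixel_size = 100)
  cov <- matrix(0, 4, 4)
  cov[, 1:2] <- c(1, 3)          # zone-1 pixels alternate 1, 3
  cov[, 3:4] <- 5
  lay <- grid_raster(cov, pixel_size = 100)
  stack <- covariate_stack(1990, list(covA = lay))
  census <- harmonized_census(c(`1` = 80, `2` = 1000), year = 1990)
  tab <- zonal_summarize(stack, zones, census)
  expect_equal(tab$covA, c(2, 5))
  expect_equal(tab$pixel_count, c(8L, 8L))
  expect_equal(tab$log_density, c(log(10), log(125)))
  expect_equal(tab$area_ha, c(8, 8))

  # ln(10) example at the spec scale: 1000 people over 100 usable pixels
  zones2 <- grid_raster(matrix(1, 10, 10), pixel_size = 100)
  stack2 <- covariate_stack(1990, list(covA = grid_raster(matrix(0, 10, 10),
                                                          pixel_size = 100)))
  tab2 <- zonal_summarize(stack2, zones2, harmonized_census(c(`1` = 1000)))
  expect_equal(tab2$log_density, log(10), tolerance = 1e-12)
})

test_that("zonal summaries match a per-pixel group-by oracle on random inputs", {
  set.seed(77)
  zv <- matrix(sample(1:6, 400, replace = TRUE), 20, 20)
  v1 <- matrix(stats::rnorm(400), 20, 20)
  v2 <- matrix(stats::rnorm(400), 20, 20)
  v2[sample(400, 30)] <- NA
  zones <- grid_raster(zv, pixel_size = 100)
  stack <- covariate_stack(2000, list(a = grid_raster(v1, pixel_size = 100),
                                      b = grid_raster(v2, pixel_size = 100)))
  census <- harmonized_census(stats::setNames(rep(100, 6), 1:6))
  tab <- zonal_summarize(stack, zones, census)
  usable <- !is.na(v2)
  for (z in 1:6) {
    sel <- zv == z & usable
    expect_equal(tab$a[tab$zone_id == z], mean(v1[sel]))
    expect_equal(tab$b[tab$zone_id == z], mean(v2[sel]))
    expect_equal(tab$pixel_count[tab$zone_id == z], sum(sel))
  }
})

test_that("zonal summaries error on missing census ids and exclude zero counts", {
  zones <- grid_raster(matrix(c(1, 2), 4, 4), pixel_size = 100)
  stack <- covariate_stack(1990, list(a = grid_raster(matrix(1, 4, 4),
                                                      pixel_size = 100)))
  expect_error(zonal_summarize(stack, zones, harmonized_census(c(`1` = 5))),
               "census count missing")
  tab <- suppressMessages(
    zonal_summarize(stack, zones, harmonized_census(c(`1` = 5, `2` = 0))))
  expect_equal(tab$zone_id, 1)
  expect_equal(attr(tab, "excluded"), 2)
})

test_that("the forest uses the stated ensemble defaults and is seed-deterministic", {
  tab <- make_toy_table(50, function(x) 2 * x, sigma = 0.1)
  m <- fit_forest(tab, seed = 5)
  expect_equal(m$n_trees, 500)
  expect_equal(m$rf$ntree, 500)
  expect_equal(m$min_node_size, 1)
  expect_equal(m$mtry, 1)                    # all covariates
  m2 <- fit_forest(tab, seed = 5)
  expect_identical(m$oob_predictions, m2$oob_predictions)
  m3 <- fit_forest(tab, seed = 6)
  expect_false(identical(m$oob_predictions, m3$oob_predictions))
  expect_error(fit_forest(make_toy_table(10, identity)), "fewer than 20")
})

test_that("a noiseless linear signal is recovered with high OOB variance explained", {
  tab <- make_toy_table(200, function(x) 2 * x, sigma = 0)
  m <- fit_forest(tab, seed = 11)
  e <- oob_error(m, tab)
  expect_gte(e$variance_explained, 0.90)
})

test_that("OOB error arithmetic matches its definition", {
  tab <- make_toy_table(30, function(x) x)
  y <- tab$log_density
  perfect <- list(oob_predictions = y)
  expect_equal(oob_error(perfect, tab), list(mse_log = 0, variance_explained = 1))
  null_model <- list(oob_predictions = rep(mean(y), length(y)))
  expect_equal(oob_error(null_model, tab)$variance_explained, 0)
  # toy residuals [1, -1] on y = [0, 2]: mse 1, variance explained 0
  toy <- tab[1:2, ]
  toy$log_density <- c(0, 2)
  stub <- list(oob_predictions = c(1, 1))
  e <- oob_error(stub, toy)
  expect_equal(e$mse_log, 1)
  expect_equal(e$variance_explained, 0)
})

test_that("permutation importance separates signal from noise deterministically", {
  tab <- make_toy_table(150, function(x) 3 * x, sigma = 0.1, seed = 9,
                        extra_noise_covs = 3)
  m <- fit_forest(tab, seed = 13)
  imp <- permutation_importance(m, tab, n_repeats = 10, seed = 17)
  v <- unclass(imp)
  expect_named(v, c("cov1", "noise1", "noise2", "noise3"))
  expect_equal(names(which.max(v)), "cov1")          # sole signal ranks first
  expect_true(all(abs(v[c("noise1", "noise2", "noise3")]) <= 5))
  imp2 <- permutation_importance(m, tab, n_repeats = 10, seed = 17)
  expect_identical(unclass(imp), unclass(imp2))
  # agreement with the ensemble's own importance measure on the top covariate
  set.seed(13)
  rf <- randomForest::randomForest(x = tab[, attr(tab, "covariates")],
                                   y = tab$log_density, ntree = 500,
                                   mtry = 4, nodesize = 1, importance = TRUE)
  own <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  expect_equal(names(which.max(own)), names(which.max(v)))
})

test_that("the internal tree traversal reproduces randomForest predictions", {
  tab <- make_toy_table(60, function(x) 2 * x, sigma = 0.1, seed = 21,
                        extra_noise_covs = 1)
  m <- fit_forest(tab, seed = 22, n_trees = 50)
  X <- as.matrix(tab[, attr(tab, "covariates")])
  ind <- predict(m$rf, as.data.frame(X), predict.all = TRUE)$individual
  for (k in c(1, 25, 50)) {
    tr <- randomForest::getTree(m$rf, k, labelVar = FALSE)
    expect_equal(dasypop:::tree_predict(tr, X), unname(ind[, k]),
                 tolerance = 1e-12)
  }
})

test_that("the identity permutation hook yields exactly zero importance", {
  tab <- make_toy_table(40, function(x) x, sigma = 0.2, extra_noise_covs = 1)
  m <- fit_forest(tab, seed = 3)
  imp <- permutation_importance(m, tab, n_repeats = 2, seed = 4,
                                permutation = "identity")
  expect_identical(max(abs(unclass(imp))), 0)
})

test_that("the predicted density surface is positive, masked, and name-checked", {
  fit <- small_world_fit(1)
  w <- fit$weights
  expect_true(all(w$values[!is.na(w$values)] > 0))

  # constant covariates -> constant surface
  const_stack <- covariate_stack(1990, stats::setNames(
    lapply(fit$model$covariates, function(nm)
      grid_raster(matrix(1, 5, 5), pixel_size = 100)),
    fit$model$covariates))
  cw <- predict_density_surface(fit$model, const_stack)
  expect_equal(max(cw$values) - min(cw$values), 0)

  # an NA pixel in any layer is NA in the output
  na_stack <- const_stack
  na_stack$layers[[2]]$values[3, 3] <- NA
  nw <- predict_density_surface(fit$model, na_stack)
  expect_true(is.na(nw$values[3, 3]))
  expect_equal(sum(is.na(nw$values)), 1)

  bad <- const_stack
  names(bad$layers)[1] <- "wrong_name"
  expect_error(predict_density_surface(fit$model, bad), "do not match")
})

test_that("predicted weights decrease with distance to the built edge", {
  fit <- small_world_fit(1)
  d <- fit$stack$layers$built_dist_1990$values
  w <- fit$weights$values
  ok <- !is.na(d) & !is.na(w)
  bins <- cut(d[ok], breaks = stats::quantile(d[ok], probs = seq(0, 1, 0.1)),
              include.lowest = TRUE)
  mw <- tapply(w[ok], bins, mean)
  rho <- stats::cor(seq_along(mw), as.numeric(mw), method = "spearman")
  expect_lte(rho, -0.9)
})

test_that("per-year fits are independent of other years' data", {
  fit <- small_world_fit(1)
  m_again <- fit_forest(fit$table, seed = fit$model$seed)
  expect_identical(m_again$oob_predictions, fit$model$oob_predictions)
  w2 <- predict_density_surface(m_again, fit$stack)
  expect_identical(w2$values, fit$weights$values)
})
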