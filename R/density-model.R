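#' Zonal covariate summary and log population density
#'
#' Builds the model's training table: one row per zone with, over the zone's
#' usable pixels (non-`NA` in every stack layer), the mean of each covariate,
#' the usable pixel count, the zone area in hectares, the harmonized count and
#' the response `log_density = ln(count / pixel_count)` (natural log, people
#' per pixel). Zones with no usable pixels or a non-positive count are
#' excluded from the table (they still receive predictions later) and listed
#' in the `excluded` attribute.
#'
#' @param stack A [covariate_stack()].
#' @param zones A zone-id `grid_raster` aligned with the stack.
#' @param census A [harmonized_census()] covering every zone id present in
#'   `zones` (a zone with pixels but no census entry is an error).
#' @return A data.frame of class `zonal_table`; attribute `covariates` names
#'   the predictor columns.
#' @export
zonal_summarize <- function(stack, zones, census) {
  stopifnot(inherits(stack, "covariate_stack"), inherits(zones, "grid_raster"),
            inherits(census, "harmonized_census"))
  l1 <- stack$layers[[1]]
  if (!same_grid(l1, zones)) stop("zones raster is not aligned with the stack")
  usable <- Reduce(`&`, lapply(stack$layers, function(l) !is.na(l$values)))
  zv <- zones$values
  zone_ids <- sort(unique(zv[!is.na(zv)]))
  missing <- setdiff(as.character(zone_ids), names(census$counts))
  if (length(missing) > 0)
    stop("census count missing for zone id(s): ", paste(missing, collapse = ", "))

  idx <- !is.na(zv) & usable
  zf <- factor(zv[idx], levels = zone_ids)
  pix <- as.integer(table(zf))
  means <- vapply(stack$layers, function(l) {
    as.numeric(tapply(l$values[idx], zf, mean))
  }, numeric(length(zone_ids)))
  if (is.null(dim(means))) means <- matrix(means, nrow = length(zone_ids))
  colnames(means) <- names(stack$layers)

  counts <- as.numeric(census$counts[as.character(zone_ids)])
  keep <- pix >= 1 & counts > 0
  excluded <- zone_ids[!keep]
  if (length(excluded) > 0)
    dp_log("zonal_summarize: excluding %d zone(s) with no usable pixels or zero count",
           length(excluded))
  px <- l1$pixel_size
  tab <- data.frame(zone_id = zone_ids[keep],
                    pixel_count = pix[keep],
                    area_ha = pix[keep] * px^2 / 1e4)
  tab <- cbind(tab, as.data.frame(means[keep, , drop = FALSE]))
  tab$count <- counts[keep]
  tab$log_density <- log(tab$count / tab$pixel_count)
  rownames(tab) <- NULL
  structure(tab, class = c("zonal_table", "data.frame"),
            covariates = names(stack$layers), pixel_size = px,
            excluded = excluded)
}

#' Fit the per-year Random Forest density model
#'
#' Bootstrap ensemble of unpruned regression trees relating unit-level log
#' population density to the zonal covariate means: 500 trees, terminal nodes
#' grown to a single observation, and all covariates candidate at every split
#' (defaults; overridable). Out-of-bag predictions — the mean over trees whose
#' bootstrap sample excluded the row — are stored for error reporting and
#' permutation importance. Deterministic given `seed`.
#'
#' @param table A [zonal_summarize()] table with >= 20 rows.
#' @param seed Integer RNG seed.
#' @param n_trees,min_node_size Ensemble size and terminal node size.
#' @param mtry Covariates tried per split; default all of them.
#' @return Object of class `forest_model`.
#' @export
fit_forest <- function(table, seed = 1L, n_trees = 500L, min_node_size = 1L,
                       mtry = NULL) {
  covs <- attr(table, "covariates")
  if (is.null(covs)) covs <- setdiff(names(table),
                                     c("zone_id", "pixel_count", "area_ha",
                                       "count", "log_density", "year"))
  if (length(covs) < 1) stop("at least one covariate required")
  if (nrow(table) < 20) stop("fewer than 20 training rows")
  x <- as.data.frame(table[, covs, drop = FALSE])
  y <- table$log_density
  if (any(!is.finite(y))) stop("non-finite log_density in training table")
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y,
    ntree = n_trees, mtry = mtry %||% length(covs), nodesize = min_node_size,
    keep.forest = TRUE, keep.inbag = TRUE
  )
  structure(
    list(rf = rf, covariates = covs, n_trees = n_trees,
         min_node_size = min_node_size, mtry = mtry %||% length(covs),
         seed = seed, oob_predictions = unname(rf$predicted)),
    class = "forest_model"
  )
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, node size %d, mtry %d, %d covariates\n",
              x$n_trees, x$min_node_size, x$mtry, length(x$covariates)))
  invisible(x)
}

#' Out-of-bag error of a fitted density model
#'
#' `mse_log` is the mean squared OOB residual of log density;
#' `variance_explained` is `1 - mse_log / pop-variance(log_density)` (the OOB
#' analogue of R^2; `NA` for a constant response).
#'
#' @param model A [fit_forest()] model.
#' @param table The table it was fitted on.
#' @return List with `mse_log` and `variance_explained`.
#' @export
oob_error <- function(model, table) {
  y <- table$log_density
  pred <- model$oob_predictions
  if (length(pred) != length(y)) stop("model was not fitted on this table")
  mse <- mean((pred - y)^2)
  vy <- mean((y - mean(y))^2)
  list(mse_log = mse,
       variance_explained = if (vy > 0) 1 - mse / vy else NA_real_)
}

# vectorised traversal of one extracted regression tree (numeric splits only):
# rows at non-terminal nodes follow `x <= split point` to the left daughter
tree_predict <- function(tr, X) {
  node <- rep(1L, nrow(X))
  repeat {
    act <- which(tr[node, 5L] != -1L)          # status -1 marks terminal nodes
    if (length(act) == 0) break
    sv <- tr[node[act], 3L]
    goleft <- X[cbind(act, sv)] <= tr[node[act], 4L]
    node[act] <- ifelse(goleft, tr[node[act], 1L], tr[node[act], 2L])
  }
  unname(tr[node, 6L])
}

#' Permutation importance as percent increase in OOB MSE
#'
#' Classic out-of-bag permutation importance: for each covariate, every tree's
#' out-of-bag rows have that covariate permuted among themselves, the tree
#' re-scores them, and the ensemble OOB MSE is recomputed from the per-tree
#' OOB predictions. The reported importance is
#' `100 * (MSE_perm - MSE_orig) / MSE_orig`, averaged over `n_repeats`
#' independent sets of per-tree permutations. Deterministic given `seed`.
#' `permutation = "identity"` is a degeneracy hook: every tree scores its
#' unpermuted rows, so every importance is exactly 0.
#'
#' @param model A [fit_forest()] model (fitted with inbag records, as
#'   [fit_forest()] always does).
#' @param table The table the model was fitted on.
#' @param n_repeats Permutation sets averaged per covariate.
#' @param seed Integer RNG seed.
#' @param permutation `"random"` (default) or `"identity"`.
#' @return Named numeric vector (class `importance_table`), one entry per
#'   covariate, in percent.
#' @export
permutation_importance <- function(model, table, n_repeats = 5L, seed = 1L,
                                   permutation = c("random", "identity")) {
  permutation <- match.arg(permutation)
  X <- as.matrix(table[, model$covariates, drop = FALSE])
  if (!is.numeric(X)) stop("covariates must be numeric")
  y <- table$log_density
  n <- nrow(X)
  inbag <- model$rf$inbag
  if (is.null(inbag)) stop("model lacks inbag records")
  ntree <- model$rf$ntree
  oob_rows <- lapply(seq_len(ntree), function(k) which(inbag[, k] == 0))
  w <- tabulate(unlist(oob_rows), n)
  if (any(w == 0)) stop("a row is out of bag in no tree; increase n_trees")
  trees <- lapply(seq_len(ntree), function(k)
    randomForest::getTree(model$rf, k, labelVar = FALSE))

  # per-tree OOB predictions on the unpermuted data
  pred_orig <- numeric(n)
  for (k in seq_len(ntree)) {
    o <- oob_rows[[k]]
    pred_orig[o] <- pred_orig[o] + tree_predict(trees[[k]], X[o, , drop = FALSE])
  }
  mse_orig <- mean((pred_orig / w - y)^2)

  set.seed(seed)
  p <- length(model$covariates)
  imp <- matrix(0, p, n_repeats, dimnames = list(model$covariates, NULL))
  for (r in seq_len(n_repeats)) {
    for (j in seq_len(p)) {
      acc <- numeric(n)
      for (k in seq_len(ntree)) {
        o <- oob_rows[[k]]
        Xp <- X[o, , drop = FALSE]
        if (permutation == "random")
          Xp[, j] <- Xp[sample.int(length(o)), j]
        acc[o] <- acc[o] + tree_predict(trees[[k]], Xp)
      }
      mse_perm <- mean((acc / w - y)^2)
      imp[j, r] <- 100 * (mse_perm - mse_orig) / mse_orig
    }
  }
  structure(rowMeans(imp), class = "importance_table")
}

#' Predict the pixel-level density surface (the dasymetric weighting layer)
#'
#' Applies the fitted forest to every usable pixel of the stack (non-`NA` in
#' all layers) and back-transforms with `exp`, giving a strictly positive
#' predicted density wherever defined; unusable pixels are `NA`. Each year's
#' surface comes from that year's own model — models are never reused across
#' years.
#'
#' @param model A [fit_forest()] model.
#' @param stack A [covariate_stack()] whose layer names match the model's
#'   covariates exactly.
#' @return A `grid_raster` weighting layer (people-per-pixel scale).
#' @export
predict_density_surface <- function(model, stack) {
  lname <- names(stack$layers)
  if (!setequal(lname, model$covariates))
    stop("stack layers do not match model covariates; model has {",
         paste(model$covariates, collapse = ", "), "}, stack has {",
         paste(lname, collapse = ", "), "}")
  tmpl <- stack$layers[[1]]
  usable <- Reduce(`&`, lapply(stack$layers, function(l) !is.na(l$values)))
  idx <- which(usable)
  newdata <- as.data.frame(lapply(stack$layers[model$covariates],
                                  function(l) l$values[idx]))
  names(newdata) <- model$covariates
  pred <- predict(model$rf, newdata)
  out <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  out[idx] <- exp(pred)
  with_values(tmpl, out)
}

#' Write the per-year model card (JSON)
#'
#' Hyperparameters, seed, covariate names, OOB error, variance explained and
#' the importance table, in one machine-readable file per fitted year.
#'
#' @param model A [fit_forest()] model.
#' @param err [oob_error()] result.
#' @param importance [permutation_importance()] result.
#' @param year Year label.
#' @param path Output JSON path.
#' @export
write_model_card <- function(model, err, importance, year, path) {
  card <- list(
    year = year,
    n_trees = model$n_trees,
    min_node_size = model$min_node_size,
    mtry = model$mtry,
    seed = model$seed,
    covariates = model$covariates,
    oob_mse_log = err$mse_log,
    variance_explained = err$variance_explained,
    importance_pct_inc_mse = as.list(unclass(importance))
  )
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
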