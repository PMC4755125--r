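#' Harmonized census counts on the fixed target zone set
#'
#' @param counts Named numeric vector (names = target zone ids), one entry per
#'   target zone, possibly zero; non-negative.
#' @param year Year label.
#' @param source_total Total of the source counts before reallocation.
#' @param unallocated Count mass that intersected no target.
#' @return Object of class `harmonized_census`.
#' @export
harmonized_census <- function(counts, year = NA, source_total = sum(counts),
                              unallocated = 0) {
  if (is.null(names(counts))) stop("counts must be named by target zone id")
  if (any(counts < 0)) stop("harmonized counts must be non-negative")
  structure(list(counts = counts, year = year, source_total = source_total,
                 unallocated = unallocated),
            class = "harmonized_census")
}

#' @export
print.harmonized_census <- function(x, ...) {
  cat(sprintf("<harmonized_census> year %s: %d zones, total %.6g (unallocated %.6g)\n",
              as.character(x$year), length(x$counts), sum(x$counts), x$unallocated))
  invisible(x)
}

#' Reallocate census counts onto a fixed target zone set
#'
#' Transfers counts from source census units to target zones by areal
#' interpolation: a source whose area falls (to within `containment` of its
#' area) inside a single target is assigned completely to that target;
#' otherwise its count is split across targets in proportion to the
#' intersection area with each. Count mass intersecting no target is tracked
#' as `unallocated` (with a warning), so
#' `sum(harmonized) == sum(source) - unallocated` holds exactly up to floating
#' point.
#'
#' @param sources A [polygon_set()] of source census units.
#' @param counts Numeric vector of source population counts, aligned with
#'   `sources$ids` (or named by source id).
#' @param targets A [polygon_set()] of target zones tiling the study area.
#' @param year Year label carried onto the result.
#' @param containment Fraction of a source's area that must fall inside one
#'   target for whole-count assignment (absorbs digitised-boundary slivers).
#' @return A [harmonized_census()] with one (possibly zero) entry per target.
#' @export
reallocate_counts <- function(sources, counts, targets, year = NA,
                              containment = 0.999) {
  stopifnot(inherits(sources, "polygon_set"), inherits(targets, "polygon_set"))
  if (!identical(sources$crs, targets$crs))
    stop("sources and targets must share a CRS")
  if (!is.null(names(counts))) counts <- counts[as.character(sources$ids)]
  if (length(counts) != length(sources$ids))
    stop("one count per source unit required")
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")

  tgt_ids <- targets$ids
  out <- stats::setNames(numeric(length(tgt_ids)), as.character(tgt_ids))
  tgt_bb <- lapply(targets$polygons, poly_bbox)
  unallocated <- 0

  for (s in seq_along(sources$ids)) {
    src <- sources$polygons[[s]]
    a_src <- poly_area(src)
    bb <- poly_bbox(src)
    inter <- numeric(length(tgt_ids))
    for (t in seq_along(tgt_ids)) {
      if (bbox_disjoint(bb, tgt_bb[[t]])) next
      inter[t] <- poly_intersection_area(src, targets$polygons[[t]])
    }
    covered <- sum(inter) / a_src
    if (covered <= 0) {
      warning("source unit ", sources$ids[s],
              " intersects no target; count left unallocated")
      unallocated <- unallocated + counts[s]
      next
    }
    best <- which.max(inter)
    if (inter[best] / a_src >= containment) {
      # falling within a single target: assigned completely to that unit
      out[best] <- out[best] + counts[s]
    } else {
      out <- out + counts[s] * inter / a_src
      if (covered < 1 - 1e-9)
        unallocated <- unallocated + counts[s] * (1 - covered)
    }
  }
  harmonized_census(out, year = year, source_total = sum(counts),
                    unallocated = unallocated)
}

#' Average spatial resolution of a census tessellation
#'
#' The side length of the mean square unit, `sqrt(total_area / n_units)`: a
#' single-number summary of how fine an administrative tessellation is.
#'
#' @param total_area Total study area in km^2 (> 0).
#' @param n_units Number of administrative units (>= 1).
#' @return ASR in km.
#' @export
compute_asr <- function(total_area, n_units) {
  if (!is.numeric(total_area) || total_area <= 0) stop("total_area must be > 0")
  if (!is_count(n_units) || n_units < 1) stop("n_units must be a positive integer")
  sqrt(total_area / n_units)
}

#' Read a census table (unit_id, population, year) from CSV
#' @param path CSV path.
#' @export
read_census_csv <- function(path) {
  stop_if_missing_file(path, "census table")
  df <- utils::read.csv(path)
  need <- c("unit_id", "population", "year")
  if (!all(need %in% names(df)))
    stop("census CSV must have columns unit_id, population, year: ", path)
  df
}

#' Write a census table to CSV
#' @param df Data frame with unit_id, population, year.
#' @param path Output path.
#' @export
write_census_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
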