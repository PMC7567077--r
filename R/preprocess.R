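#' Nearest-neighbour-distance thinning of occurrence records
#'
#' Removes spatially clustered records to reduce sampling bias: within each
#' species x status group, a greedy pass in input order keeps a point only
#' if its planar Euclidean distance (degrees) to every previously kept point
#' is strictly greater than `min_dist`. All kept pairs therefore satisfy a
#' nearest-neighbour distance above the threshold, and the operation is
#' idempotent. The default 0.02 degrees is roughly 2 km at the equator,
#' below the resolution of 2.5 arc-minute climate grids.
#'
#' @param occ Occurrence data.frame (`species,status,lon,lat`).
#' @param min_dist Minimum allowed nearest-neighbour distance, degrees.
#' @return The thinned occurrence table, input order preserved.
#' @export
#' @examples
#' occ <- data.frame(species = "a", status = "native",
#'                   lon = c(0, 0, 0), lat = c(0, 0.01, 1))
#' thin_nnd(occ) # drops the point 0.01 degrees from the first
thin_nnd <- function(occ, min_dist = 0.02) {
  .check_occ(occ)
  if (min_dist < 0) stop("min_dist must be non-negative")
  if (nrow(occ) == 0L) stop("empty occurrence table")
  keep <- logical(nrow(occ))
  grp <- interaction(occ$species, occ$status, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    kept_lon <- numeric(0)
    kept_lat <- numeric(0)
    for (i in idx) {
      if (length(kept_lon) == 0L ||
          min(sqrt((kept_lon - occ$lon[i])^2 + (kept_lat - occ$lat[i])^2)) > min_dist) {
        keep[i] <- TRUE
        kept_lon <- c(kept_lon, occ$lon[i])
        kept_lat <- c(kept_lat, occ$lat[i])
      }
    }
  }
  occ[keep, , drop = FALSE]
}

#' Collapse duplicate records within climate grid cells
#'
#' Keeps at most one record per species x status x raster cell (the first in
#' input order). Points outside the raster extent are dropped and counted in
#' the `dropped_outside` attribute.
#'
#' @param occ Occurrence data.frame.
#' @param stack A [climate_stack()] defining the cell geometry.
#' @return Deduplicated occurrence table with attribute `dropped_outside`.
#' @export
dedupe_grid_cells <- function(occ, stack) {
  .check_occ(occ)
  stopifnot(inherits(stack, "climate_stack"))
  if (nrow(occ) == 0L) {
    attr(occ, "dropped_outside") <- 0L
    return(occ)
  }
  ci <- cell_index(stack, occ$lon, occ$lat)
  inside <- ci$inside
  n_out <- sum(!inside)
  if (n_out > 0L) {
    message(n_out, " occurrence(s) outside the raster extent dropped")
  }
  occ2 <- occ[inside, , drop = FALSE]
  key <- paste(occ2$species, occ2$status,
               ci$row[inside], ci$col[inside], sep = "\r")
  out <- occ2[!duplicated(key), , drop = FALSE]
  attr(out, "dropped_outside") <- n_out
  out
}

#' Drop species with too few native or non-native records
#'
#' A species is retained only when it has at least `min_n` native and at
#' least `min_n` non-native records (after thinning and deduplication);
#' niche metrics on smaller samples are unreliable.
#'
#' @param occ Occurrence data.frame.
#' @param min_n Minimum records required in each range (default 10).
#' @return List with `occ` (filtered table) and `dropped` (character vector
#'   of removed species).
#' @export
filter_min_occurrences <- function(occ, min_n = 10L) {
  .check_occ(occ)
  stopifnot(min_n >= 1L)
  if (nrow(occ) == 0L) {
    return(list(occ = occ, dropped = character(0)))
  }
  tab <- table(occ$species, factor(occ$status, c("native", "nonnative")))
  ok <- rownames(tab)[tab[, "native"] >= min_n & tab[, "nonnative"] >= min_n]
  dropped <- setdiff(unique(occ$species), ok)
  list(occ = occ[occ$species %in% ok, , drop = FALSE], dropped = dropped)
}

#' Extract environmental values at occurrence points
#'
#' Nearest-cell (containing-cell) lookup of every retained climate layer.
#' Rows that fall on nodata cells are removed and counted.
#'
#' @param occ Cleaned occurrence data.frame (all points inside the extent).
#' @param stack A [climate_stack()].
#' @return Numeric matrix, one row per surviving occurrence, one column per
#'   layer; attributes `occ_index` (row index into `occ`), `dropped_nodata`.
#' @export
extract_env <- function(occ, stack) {
  .check_occ(occ)
  ci <- cell_index(stack, occ$lon, occ$lat)
  if (any(!ci$inside)) stop("occurrences outside the raster extent; clean first")
  lin <- cbind(ci$row, ci$col)
  valid <- stack$mask[lin]
  if (!any(valid)) stop("all occurrences fall on nodata cells")
  env <- vapply(stack$values, function(m) m[lin[valid, , drop = FALSE]],
                numeric(sum(valid)))
  env <- matrix(env, nrow = sum(valid),
                dimnames = list(NULL, stack$layer_names))
  attr(env, "occ_index") <- which(valid)
  attr(env, "dropped_nodata") <- sum(!valid)
  env
}

#' Run the full occurrence-cleaning chain
#'
#' Applies, in order: nearest-neighbour thinning, per-cell deduplication,
#' and the minimum-occurrence filter, and returns the cleaned table together
#' with a per-rule cleaning report.
#'
#' @param occ Raw occurrence data.frame.
#' @param stack A [climate_stack()].
#' @param min_dist Thinning distance, degrees.
#' @param min_n Minimum per-range sample size.
#' @param exclude Optional data.frame of records to exclude before cleaning
#'   (matched on species, lon, lat) - manual curation hook.
#' @return List with `occ` (cleaned table), `dropped_species`, and `report`
#'   (counts dropped per rule).
#' @export
preprocess_occurrences <- function(occ, stack, min_dist = 0.02, min_n = 10L,
                                   exclude = NULL) {
  .check_occ(occ)
  n0 <- nrow(occ)
  n_excl <- 0L
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    key <- function(d) paste(d$species, d$lon, d$lat, sep = "\r")
    drop <- key(occ) %in% key(exclude)
    n_excl <- sum(drop)
    occ <- occ[!drop, , drop = FALSE]
  }
  thinned <- thin_nnd(occ, min_dist)
  deduped <- dedupe_grid_cells(thinned, stack)
  filt <- filter_min_occurrences(deduped, min_n)
  report <- list(
    input = n0,
    excluded_manual = n_excl,
    dropped_thinning = nrow(occ) - nrow(thinned),
    dropped_outside_extent = attr(deduped, "dropped_outside"),
    dropped_cell_duplicates = nrow(thinned) - nrow(deduped) -
      attr(deduped, "dropped_outside"),
    dropped_min_occurrences = nrow(deduped) - nrow(filt$occ),
    output = nrow(filt$occ),
    dropped_species = filt$dropped
  )
  list(occ = filt$occ, dropped_species = filt$dropped, report = report)
}
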