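#' Polygons occupied by a species
#'
#' A polygon counts as occupied when at least one (cleaned, optionally
#' status-filtered) occurrence falls inside it, boundaries included.
#' Occurrences falling in no polygon are counted and ignored.
#'
#' @param occ Occurrence data.frame (one species or pre-filtered).
#' @param polygons A [range_polygons()].
#' @param status Optional status filter, `"native"` or `"nonnative"`.
#' @return List with `ids` (occupied polygon ids), `richness` (count), and
#'   `unmatched` (occurrences in no polygon).
#' @export
occupied_polygons <- function(occ, polygons, status = NULL) {
  stopifnot(inherits(polygons, "range_polygons"),
            length(polygons$ids) >= 1L)
  .check_occ(occ)
  if (!is.null(status)) occ <- occ[occ$status == status, , drop = FALSE]
  if (nrow(occ) == 0L) {
    return(list(ids = character(0), richness = 0L, unmatched = 0L))
  }
  hit <- logical(length(polygons$ids))
  unmatched <- 0L
  for (i in seq_len(nrow(occ))) {
    found <- FALSE
    for (j in seq_along(polygons$ids)) {
      if (.point_in_ring(occ$lon[i], occ$lat[i], polygons$rings[[j]])) {
        hit[j] <- TRUE
        found <- TRUE
        break
      }
    }
    if (!found) unmatched <- unmatched + 1L
  }
  if (unmatched > 0L) {
    message(unmatched, " occurrence(s) matched no polygon")
  }
  list(ids = polygons$ids[hit], richness = sum(hit), unmatched = unmatched)
}

#' Rao quadratic entropy of occupied polygon centroids
#'
#' `Q = sum_i sum_j p_i p_j d_ij`, where `d_ij` is the great-circle
#' (haversine, Earth radius 6371 km) distance between centroids i and j and
#' `p` are polygon weights (uniform by default). Q jointly captures how many
#' polygons a species occupies and how far apart they are: one polygon gives
#' Q = 0; two polygons a distance d apart give Q = d/2.
#'
#' @param centroids Two-column matrix or data.frame of centroid lon/lat
#'   (degrees), one row per occupied polygon.
#' @param weights Optional probability weights summing to 1 (default
#'   uniform).
#' @return Scalar Q in kilometres.
#' @export
rao_entropy <- function(centroids, weights = NULL) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  stopifnot(n >= 1L, ncol(centroids) == 2L)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (n == 1L) return(0)
  d <- .gc_dist_km(centroids)
  as.numeric(t(weights) %*% d %*% weights)
}

#' Classify species into geographic dispersion groups
#'
#' Species are placed in a richness-diversity space (number of occupied
#' polygons vs Rao quadratic entropy of the whole range), standardised, and
#' split by k-means into `k` groups labelled `regional`, `transcontinental`
#' and `global` in ascending order of mean Rao entropy - increasing levels
#' of global dispersion. Records are internally sorted before clustering so
#' the labelling is invariant to input order.
#'
#' @param records data.frame with numeric columns `richness` and
#'   `rao_total` (one row per species).
#' @param k Number of groups (default 3).
#' @param seed Seed for the k-means restarts.
#' @param n_start Number of random restarts (default 25).
#' @return Character vector of group labels, one per input row.
#' @export
classify_dispersion <- function(records, k = 3L, seed = 1L, n_start = 25L) {
  stopifnot(is.data.frame(records),
            all(c("richness", "rao_total") %in% names(records)))
  n <- nrow(records)
  if (n < k) stop("fewer records than clusters")
  labels_k <- if (k == 3L) {
    c("regional", "transcontinental", "global")
  } else {
    paste0("group", seq_len(k))
  }
  x <- cbind(records$richness, records$rao_total)
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    warning("fewer distinct richness-diversity points than clusters; ",
            "assigning all species to one group")
    return(rep(labels_k[1L], n))
  }
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, sdv, "/")

  # sort so clustering is independent of the caller's row order
  ord <- order(xs[, 1], xs[, 2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  km <- stats::kmeans(xs[ord, , drop = FALSE], centers = k,
                      nstart = n_start, iter.max = 100L)
  cl_sorted <- km$cluster
  cl <- integer(n)
  cl[ord] <- cl_sorted
  mean_rao <- tapply(records$rao_total, cl, mean)
  rank_of <- rank(mean_rao, ties.method = "first")
  labels_k[rank_of[as.character(cl)]]
}
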