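#' Range polygon maps
#'
#' A `range_polygons` object is the geographic tessellation used for the
#' dispersion metrics: a set of polygons (boundary rings in lon/lat degrees)
#' with unique ids and one centroid each. It stands in for political-entity
#' polygon maps in which larger countries are split into provinces.
#'
#' @param ids Character or integer vector of unique polygon ids.
#' @param rings List of numeric matrices (columns lon, lat), one boundary
#'   ring per polygon.
#' @param centroids Optional matrix of centroid lon/lat; recomputed from the
#'   rings (area-weighted shoelace centroid) when omitted.
#' @return An object of class `range_polygons`.
#' @export
range_polygons <- function(ids, rings, centroids = NULL) {
  stopifnot(length(ids) == length(rings), !anyDuplicated(ids))
  if (is.null(centroids)) {
    centroids <- t(vapply(rings, .ring_centroid, numeric(2)))
  }
  colnames(centroids) <- c("lon", "lat")
  structure(
    list(ids = as.character(ids), rings = rings, centroids = centroids),
    class = "range_polygons"
  )
}

#' @export
print.range_polygons <- function(x, ...) {
  cat(sprintf("range_polygons: %d polygons\n", length(x$ids)))
  invisible(x)
}

# Internal: shoelace (area-weighted) centroid of a ring.
.ring_centroid <- function(ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + x[j]) * cross) / (6 * a), sum((y + y[j]) * cross) / (6 * a))
}

#' Generate a regular rectangular polygon tessellation
#'
#' @param n_x,n_y Number of tiles along longitude and latitude (>= 1).
#' @param extent List with `xmin`, `xmax`, `ymin`, `ymax` (degrees).
#' @return A [range_polygons()] with `n_x * n_y` rectangles; each centroid
#'   is the rectangle's geometric centre.
#' @export
#' @examples
#' pm <- generate_polygon_map(2, 1, list(xmin = 0, xmax = 2, ymin = 0, ymax = 1))
#' pm$centroids
generate_polygon_map <- function(n_x, n_y, extent) {
  stopifnot(n_x >= 1L, n_y >= 1L)
  if (extent$xmax <= extent$xmin || extent$ymax <= extent$ymin) {
    stop("empty extent")
  }
  dx <- (extent$xmax - extent$xmin) / n_x
  dy <- (extent$ymax - extent$ymin) / n_y
  ids <- character(n_x * n_y)
  rings <- vector("list", n_x * n_y)
  k <- 0L
  for (iy in seq_len(n_y)) {
    for (ix in seq_len(n_x)) {
      k <- k + 1L
      x0 <- extent$xmin + (ix - 1L) * dx
      y0 <- extent$ymin + (iy - 1L) * dy
      ids[k] <- sprintf("poly_%03d", k)
      rings[[k]] <- cbind(
        lon = c(x0, x0 + dx, x0 + dx, x0, x0),
        lat = c(y0, y0, y0 + dy, y0 + dy, y0)
      )
    }
  }
  range_polygons(ids, rings)
}

#' Read and write polygon maps as GeoJSON
#'
#' Polygons are stored as a GeoJSON `FeatureCollection` of `Polygon`
#' features with a `polygon_id` property. Centroids are recomputed from the
#' rings on read.
#'
#' @param polygons A [range_polygons()].
#' @param path File path (`.geojson`).
#' @return `write_polygons_geojson` returns `path` invisibly;
#'   `read_polygons_geojson` returns a [range_polygons()].
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(seq_along(polygons$ids), function(i) {
    ring <- polygons$rings[[i]]
    if (!(ring[1, 1] == ring[nrow(ring), 1] &&
          ring[1, 2] == ring[nrow(ring), 2])) {
      ring <- rbind(ring, ring[1, ])
    }
    list(
      type = "Feature",
      properties = list(polygon_id = polygons$ids[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(r) as.numeric(ring[r, ])))
      )
    )
  })
  obj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(obj$type, "FeatureCollection"))
  ids <- vapply(obj$features, function(f) as.character(f$properties$polygon_id),
                character(1))
  rings <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- t(vapply(ring, function(p) as.numeric(unlist(p)), numeric(2)))
    colnames(m) <- c("lon", "lat")
    m
  })
  range_polygons(ids, rings)
}
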