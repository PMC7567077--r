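#' Derive a stage-specific random seed from a master seed
#'
#' Stochastic stages of the pipeline each draw their own seed from the run's
#' master seed plus a stage label (and optionally a per-species index), so
#' that adding or removing one species never perturbs the random draws of
#' another.
#'
#' @param master Integer master seed.
#' @param stage Character stage label, e.g. `"equivalency"`.
#' @param index Optional integer sub-index (species number, trial number).
#' @return A single integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' stage_seed(1L, "equivalency", 3L)
stage_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime keeps the modular arithmetic exact
  h <- (as.numeric(master) %% m)
  for (b in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + b) %% m
  }
  h <- (h * 31 + (as.numeric(index) %% m)) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: great-circle distance matrix (km) between rows of a lon/lat matrix.
# Haversine on a sphere of radius 6371 km.
.gc_dist_km <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  if (n < 2L) {
    return(d)
  }
  for (i in seq_len(n - 1L)) {
    dk <- geosphere::distHaversine(coords[i, , drop = FALSE],
                                   coords[(i + 1L):n, , drop = FALSE],
                                   r = 6371000) / 1000
    d[i, (i + 1L):n] <- dk
    d[(i + 1L):n, i] <- dk
  }
  d
}

# Internal: ray-casting point-in-polygon, boundary counted as inside.
# ring: matrix with columns lon, lat (closed or open ring both accepted).
.point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    n <- n - 1L
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    # boundary check: point on segment (i, j)
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cross) < 1e-12 &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12) {
      return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Internal: assert a data.frame is a valid occurrence table.
.check_occ <- function(occ) {
  stopifnot(is.data.frame(occ))
  need <- c("species", "status", "lon", "lat")
  if (!all(need %in% names(occ))) {
    stop("occurrence table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(occ) > 0L) {
    bad <- !(occ$status %in% c("native", "nonnative"))
    if (any(bad)) stop("status must be 'native' or 'nonnative'")
    if (any(occ$lon < -180 | occ$lon > 180 | occ$lat < -90 | occ$lat > 90)) {
      stop("coordinates outside [-180,180] x [-90,90]")
    }
  }
  invisible(occ)
}
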