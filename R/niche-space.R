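#' Fit the per-species discriminant climatic axis
#'
#' Climatic variables of all occurrences (native and non-native pooled) are
#' standardised and reduced by PCA; a between-class analysis on the leading
#' `n_axes` principal components with the two range classes as a priori
#' groups then yields the single axis separating the ranges the most. For
#' two classes the between-class direction is the difference of the class
#' centroids in PC-score space, normalised to unit length; its sign is fixed
#' so the native centroid projects at or below the non-native centroid.
#'
#' @param env_native,env_nonnative Environmental matrices (same columns) for
#'   the native and non-native occurrences.
#' @param n_axes Number of PCA axes retained before the between-class step
#'   (default 10).
#' @return An object of class `niche_axis` with the standardisation, PCA
#'   loadings, and unit between-class vector.
#' @export
fit_species_axis <- function(env_native, env_nonnative, n_axes = 10L) {
  stopifnot(is.matrix(env_native), is.matrix(env_nonnative),
            identical(colnames(env_native), colnames(env_nonnative)))
  pooled <- rbind(env_native, env_nonnative)
  if (nrow(pooled) <= n_axes) stop("need more pooled occurrences than axes")
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(pooled)[!keep], collapse = ", "))
  }
  vars <- colnames(pooled)[keep]
  x <- sweep(sweep(pooled[, keep, drop = FALSE], 2, mu[keep]), 2,
             sdv[keep], "/")
  pca <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  n_use <- min(n_axes, ncol(pca$rotation))
  loadings <- pca$rotation[, seq_len(n_use), drop = FALSE]
  scores <- x %*% loadings
  is_nat <- rep(c(TRUE, FALSE), c(nrow(env_native), nrow(env_nonnative)))
  cen_nat <- colMeans(scores[is_nat, , drop = FALSE])
  cen_non <- colMeans(scores[!is_nat, , drop = FALSE])
  diff <- cen_non - cen_nat
  nrm <- sqrt(sum(diff^2))
  if (nrm < 1e-12) {
    warning("identical class centroids; falling back to PC1 as the niche axis")
    bca <- c(1, rep(0, n_use - 1L))
  } else {
    bca <- diff / nrm
  }
  structure(
    list(mean = mu[keep], sd = sdv[keep], vars = vars,
         loadings = loadings, bca = bca, n_axes = n_use),
    class = "niche_axis"
  )
}

#' Project environmental values onto the species niche axis
#'
#' @param env Environmental matrix whose columns include the axis variables.
#' @param axis A `niche_axis` from [fit_species_axis()].
#' @return Numeric vector of 1-D scores:
#'   `((x - mean) / sd) %*% loadings %*% bca`.
#' @export
project_axis <- function(env, axis) {
  stopifnot(inherits(axis, "niche_axis"))
  if (!all(axis$vars %in% colnames(env))) {
    stop("environmental matrix lacks the axis variables")
  }
  x <- env[, axis$vars, drop = FALSE]
  x <- sweep(sweep(x, 2, axis$mean), 2, axis$sd, "/")
  as.numeric(x %*% axis$loadings %*% axis$bca)
}

# Internal: Gaussian KDE evaluated at `at` (direct evaluation; no FFT
# binning, so tail underflow to exact zero is well defined).
.kde_at <- function(x, at, bw) {
  if (bw <= 0) stop("bandwidth must be positive")
  rowMeans(stats::dnorm(outer(at, x, "-") / bw)) / bw
}

# Internal: Silverman-type default bandwidth, robust to zero IQR.
.bw_default <- function(x) {
  b <- tryCatch(stats::bw.nrd0(x), error = function(e) NA_real_)
  if (!is.finite(b) || b <= 0) b <- max(stats::sd(x), 1e-8) * 0.5
  b
}

#' Kernel-smoothed occupancy densities on a binned niche axis
#'
#' Evaluates Gaussian kernel densities of the occurrence scores (`o`) and of
#' the available background climates (`e`) at the midpoints of `n_bins`
#' equal bins, renormalised to sum to one (the kernel is thereby truncated
#' at the grid bounds, with no boundary reflection). The occupancy `z`
#' corrects occurrence density for climate availability: `z` is proportional
#' to `o / e` where `e` exceeds a small fraction (1e-12) of the availability
#' mass and zero elsewhere, renormalised to sum to one. This controls for
#' common climates being over-represented among occurrences purely because
#' they are common.
#'
#' Occurrence and availability densities share one smoothing scale (the
#' occurrence bandwidth), so their ratio compares like with like; smoothing
#' the availability more broadly than the occurrences would dilute `e` at
#' the edges of climate space and inflate `z` exactly where data are
#' scarcest.
#'
#' @param scores_occ Occurrence scores on the niche axis (>= 2 distinct).
#' @param scores_bg Background (availability) scores on the same axis.
#' @param n_bins Number of bins (default 100).
#' @param bandwidth Kernel bandwidth used for both densities; default is
#'   Silverman's rule-of-thumb on `scores_occ`.
#' @param bounds Numeric length-2 grid bounds; defaults to the range of the
#'   pooled occurrence and background scores. Pass the same bounds for the
#'   native and non-native ranges of a species so the two densities share
#'   one grid.
#' @param correct Apply the availability correction (default `TRUE`); when
#'   `FALSE`, `z` is the raw occurrence density `o`.
#' @return An object of class `grid_density` with fields `edges`, `mid`,
#'   `o`, `e`, `z`, each density summing to one over bins.
#' @export
grid_density <- function(scores_occ, scores_bg, n_bins = 100L,
                         bandwidth = NULL, bounds = NULL, correct = TRUE) {
  if (length(unique(scores_occ)) < 2L) {
    stop("need at least 2 distinct occurrence scores")
  }
  stopifnot(length(scores_bg) >= 2L, n_bins >= 2L)
  if (is.null(bounds)) bounds <- range(c(scores_occ, scores_bg))
  stopifnot(bounds[1] < bounds[2])
  edges <- seq(bounds[1], bounds[2], length.out = n_bins + 1L)
  mid <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  if (is.null(bandwidth)) bandwidth <- .bw_default(scores_occ)
  o <- .kde_at(scores_occ, mid, bandwidth)
  e <- .kde_at(scores_bg, mid, bandwidth)
  o <- o / sum(o)
  e <- e / sum(e)
  if (correct) {
    eps <- 1e-12
    zraw <- ifelse(e > eps, o / pmax(e, eps), 0)
    if (sum(zraw) == 0) stop("no occupied bins with available climate")
    z <- zraw / sum(zraw)
  } else {
    z <- o
  }
  structure(
    list(edges = edges, mid = mid, o = o, e = e, z = z,
         bw_occ = bandwidth, corrected = correct),
    class = "grid_density"
  )
}

#' @export
print.grid_density <- function(x, ...) {
  cat(sprintf("grid_density: %d bins on [%.3g, %.3g], %d occupied\n",
              length(x$mid), x$edges[1], x$edges[length(x$edges)],
              sum(x$z > 0)))
  invisible(x)
}

#' Serialise a niche axis to JSON
#'
#' Writes the standardisation, PCA loadings and between-class vector so an
#' axis can be inspected or re-applied outside R.
#'
#' @param axis A `niche_axis` from [fit_species_axis()].
#' @param path Optional file path; when given the JSON is also written.
#' @return The JSON string, invisibly when `path` is given.
#' @export
axis_to_json <- function(axis, path = NULL) {
  stopifnot(inherits(axis, "niche_axis"))
  js <- jsonlite::toJSON(
    list(vars = axis$vars, mean = unname(axis$mean), sd = unname(axis$sd),
         loadings = unname(axis$loadings), bca = unname(axis$bca),
         n_axes = axis$n_axes),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Serialise a density grid to a data.frame / CSV
#'
#' @param gd A [grid_density()].
#' @param path Optional CSV path; when given the table is also written.
#' @return data.frame with columns `bin_mid`, `o`, `e`, `z`.
#' @export
grid_density_table <- function(gd, path = NULL) {
  stopifnot(inherits(gd, "grid_density"))
  out <- data.frame(bin_mid = gd$mid, o = gd$o, e = gd$e, z = gd$z)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

# Internal: minimum distance from point (px, py) to a polyline given as a
# two-column matrix of vertices.
.dist_to_segments <- function(px, py, verts) {
  n <- nrow(verts)
  if (n == 1L) return(sqrt((px - verts[1, 1])^2 + (py - verts[1, 2])^2))
  dmin <- Inf
  for (i in seq_len(n - 1L)) {
    ax <- verts[i, 1]; ay <- verts[i, 2]
    bx <- verts[i + 1L, 1]; by <- verts[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / L2))
    d <- sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
    if (d < dmin) dmin <- d
  }
  dmin
}

#' Background climates available to one range
#'
#' The availability sample for a range is the environment of every valid
#' raster cell whose centre lies inside the convex hull of that range's
#' occurrence points, buffered outward by `buffer_cells` cell widths (cells
#' containing occurrences are always included). Set `whole_raster = TRUE`
#' to use every valid cell instead.
#'
#' @param occ_range Occurrence data.frame for a single range (one species,
#'   one status).
#' @param stack A [climate_stack()].
#' @param buffer_cells Buffer width in cell units (default 1).
#' @param whole_raster Use the full raster as background.
#' @return Environmental matrix of the background cells (rows = cells).
#' @export
range_background <- function(occ_range, stack, buffer_cells = 1,
                             whole_raster = FALSE) {
  env <- stack_cell_env(stack)
  if (whole_raster) return(env)
  stopifnot(nrow(occ_range) >= 1L)
  pts <- unique(cbind(occ_range$lon, occ_range$lat))
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[hull_idx, , drop = FALSE]
  closed <- rbind(hull, hull[1, , drop = FALSE])
  lon <- attr(env, "lon")
  lat <- attr(env, "lat")
  buf <- buffer_cells * stack$cellsize
  sel <- logical(nrow(env))
  degenerate <- nrow(hull) < 3L
  for (i in seq_len(nrow(env))) {
    if (!degenerate && .point_in_ring(lon[i], lat[i], closed)) {
      sel[i] <- TRUE
    } else if (.dist_to_segments(lon[i], lat[i], closed) <= buf) {
      sel[i] <- TRUE
    }
  }
  # cells holding occurrences always belong to the background
  ci <- cell_index(stack, occ_range$lon, occ_range$lat)
  occ_cells <- paste(ci$row, ci$col)
  cell_key <- paste(attr(env, "row"), attr(env, "col"))
  sel[cell_key %in% occ_cells] <- TRUE
  env[sel, , drop = FALSE]
}

#' Classic two-dimensional gridded densities on PC1 x PC2
#'
#' The variant of the gridded-density framework that bins the first two
#' (pooled, standardised) principal components into an `n_bins x n_bins`
#' lattice instead of the single discriminant axis. Provided for
#' comparison with the 1-D default; Schoener's D and the expansion
#' percentage accept the flattened `z` vectors directly.
#'
#' @param env_occ Occurrence environmental matrix for one range.
#' @param env_bg Background environmental matrix for the same range.
#' @param pca A list with `mean`, `sd`, `loadings` (k x 2) defining the
#'   shared ordination, e.g. built by [pooled_pc12()].
#' @param n_bins Bins per axis (default 100).
#' @param bounds 2 x 2 matrix of grid bounds (rows = axes); pass the same
#'   bounds for both ranges of a species.
#' @param correct Apply the availability correction (default `TRUE`).
#' @return List with `z` (length `n_bins^2` occupancy, sums to 1), `o`,
#'   `e`, and the grid definition.
#' @export
grid_density_2d <- function(env_occ, env_bg, pca, n_bins = 100L,
                            bounds = NULL, correct = TRUE) {
  sc <- function(env) {
    x <- sweep(sweep(env[, names(pca$mean), drop = FALSE], 2, pca$mean),
               2, pca$sd, "/")
    x %*% pca$loadings
  }
  so <- sc(env_occ)
  sb <- sc(env_bg)
  if (is.null(bounds)) {
    bounds <- rbind(range(c(so[, 1], sb[, 1])), range(c(so[, 2], sb[, 2])))
  }
  h <- c(.bw_default(so[, 1]), .bw_default(so[, 2])) * 4  # kde2d scaling
  kd <- function(pts) {
    MASS::kde2d(pts[, 1], pts[, 2], h = h, n = n_bins,
                lims = c(bounds[1, ], bounds[2, ]))$z
  }
  o <- kd(so)
  e <- kd(sb)
  o <- o / sum(o)
  e <- e / sum(e)
  if (correct) {
    zraw <- ifelse(e > 1e-12, o / pmax(e, 1e-12), 0)
    z <- zraw / sum(zraw)
  } else {
    z <- o
  }
  list(z = as.numeric(z), o = as.numeric(o), e = as.numeric(e),
       bounds = bounds, n_bins = as.integer(n_bins))
}

#' Pooled two-axis ordination for the 2-D density variant
#'
#' @param env_nat,env_non Occurrence environmental matrices of the two
#'   ranges (pooled to fit the ordination).
#' @return List with `mean`, `sd`, `loadings` usable by
#'   [grid_density_2d()].
#' @export
pooled_pc12 <- function(env_nat, env_non) {
  pooled <- rbind(env_nat, env_non)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  keep <- sdv > 0
  x <- sweep(sweep(pooled[, keep, drop = FALSE], 2, mu[keep]), 2,
             sdv[keep], "/")
  rot <- stats::prcomp(x, center = FALSE, scale. = FALSE)$rotation
  list(mean = mu[keep], sd = sdv[keep],
       loadings = rot[, 1:2, drop = FALSE])
}

#' Build the shared native / non-native density grids for one species
#'
#' Fits the discriminant axis, projects occurrences and per-range
#' backgrounds, and evaluates both ranges' occupancy densities on one common
#' grid whose bounds span the pooled background (and occurrence) scores of
#' both ranges.
#'
#' @param env_nat,env_non Occurrence environmental matrices.
#' @param bg_nat,bg_non Background environmental matrices (e.g. from
#'   [range_background()]).
#' @param n_axes,n_bins See [fit_species_axis()] and [grid_density()].
#' @param correct Availability correction flag passed to [grid_density()].
#' @return List with `axis`, `native` and `nonnative` [grid_density()]
#'   objects (identical bin edges), and the score bounds.
#' @export
species_density_grids <- function(env_nat, env_non, bg_nat, bg_non,
                                  n_axes = 10L, n_bins = 100L,
                                  correct = TRUE) {
  axis <- fit_species_axis(env_nat, env_non, n_axes = n_axes)
  s_nat <- project_axis(env_nat, axis)
  s_non <- project_axis(env_non, axis)
  sb_nat <- project_axis(bg_nat, axis)
  sb_non <- project_axis(bg_non, axis)
  bounds <- range(c(sb_nat, sb_non, s_nat, s_non))
  list(
    axis = axis,
    native = grid_density(s_nat, sb_nat, n_bins = n_bins, bounds = bounds,
                          correct = correct),
    nonnative = grid_density(s_non, sb_non, n_bins = n_bins, bounds = bounds,
                             correct = correct),
    bounds = bounds
  )
}
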