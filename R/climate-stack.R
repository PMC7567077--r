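#' Climate raster stacks
#'
#' A `climate_stack` holds co-registered environmental layers on a shared
#' north-up geographic grid (EPSG:4326 degrees). Cells follow the half-open
#' convention `[x, x + delta) x (y - delta, y]`, rows counted from the
#' northern edge, so a point exactly on a cell's western or northern edge
#' belongs to that cell.
#'
#' @param values Named list of numeric matrices (one per layer), row 1 =
#'   northernmost row. All matrices must share dimensions.
#' @param xmin Western edge longitude of the grid (degrees).
#' @param ymax Northern edge latitude of the grid (degrees).
#' @param cellsize Cell edge length in degrees (> 0).
#' @param mask Optional logical matrix, `TRUE` where cells hold valid data;
#'   defaults to all valid. The mask is shared by every layer.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(values, xmin, ymax, cellsize, mask = NULL) {
  stopifnot(is.list(values), length(values) >= 2L)
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("layers must be uniquely named")
  }
  dims <- vapply(values, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share identical grid dimensions")
  }
  nr <- unname(dims[1, 1])
  nc <- unname(dims[2, 1])
  if (nr < 2L || nc < 2L) stop("degenerate grid: need at least 2 cells per side")
  stopifnot(cellsize > 0)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(all(dim(mask) == c(nr, nc)))
  structure(
    list(
      layer_names = names(values),
      values = values,
      xmin = xmin, ymax = ymax, cellsize = cellsize,
      nrow = nr, ncol = nc,
      mask = mask
    ),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf(
    "climate_stack: %d layers, %d x %d cells, cellsize %g deg\n  extent lon [%g, %g], lat [%g, %g]\n  layers: %s\n",
    length(x$layer_names), x$nrow, x$ncol, x$cellsize,
    x$xmin, x$xmin + x$ncol * x$cellsize,
    x$ymax - x$nrow * x$cellsize, x$ymax,
    paste(x$layer_names, collapse = ", ")
  ))
  invisible(x)
}

#' Default 17-layer bioclimatic layer names
#'
#' BIO2 and BIO7 are omitted because they are arithmetic combinations of
#' other bioclimatic variables; the remaining 17 of the 19 standard layers
#' are retained.
#'
#' @return Character vector of 17 layer labels.
#' @export
default_bioclim_layers <- function() {
  c("bio1", "bio3", "bio4", "bio5", "bio6", paste0("bio", 8:19))
}

#' Map points to raster cells
#'
#' Applies the half-open cell convention: a point on a cell's western or
#' northern edge is assigned to that cell; the grid's eastern and southern
#' outer edges are excluded.
#'
#' @param stack A [climate_stack()].
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @return A data.frame with integer columns `row`, `col` (1-based) and
#'   logical `inside`; `row`/`col` are `NA` for points outside the extent.
#' @export
cell_index <- function(stack, lon, lat) {
  cs <- stack$cellsize
  col <- floor((lon - stack$xmin) / cs) + 1L
  row <- floor((stack$ymax - lat) / cs) + 1L
  # a point exactly on the northern edge belongs to row 1
  row[lat == stack$ymax] <- 1L
  inside <- col >= 1L & col <= stack$ncol & row >= 1L & row <= stack$nrow
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = row, col = col, inside = inside)
}

# Internal: cell-center coordinates for (row, col)
.cell_center <- function(stack, row, col) {
  data.frame(
    lon = stack$xmin + (col - 0.5) * stack$cellsize,
    lat = stack$ymax - (row - 0.5) * stack$cellsize
  )
}

#' Environmental matrix of all valid cells
#'
#' @param stack A [climate_stack()].
#' @return Numeric matrix, one row per valid (unmasked) cell, one column per
#'   layer; attributes `row`, `col`, `lon`, `lat` give the cell geometry.
#' @export
stack_cell_env <- function(stack) {
  ok <- which(stack$mask)
  env <- vapply(stack$values, function(m) m[ok], numeric(length(ok)))
  env <- matrix(env, nrow = length(ok), dimnames = list(NULL, stack$layer_names))
  rc <- arrayInd(ok, c(stack$nrow, stack$ncol))
  ctr <- .cell_center(stack, rc[, 1], rc[, 2])
  attr(env, "row") <- rc[, 1]
  attr(env, "col") <- rc[, 2]
  attr(env, "lon") <- ctr$lon
  attr(env, "lat") <- ctr$lat
  env
}

#' Generate a synthetic stack of correlated smooth climate layers
#'
#' Each layer is built from a pool of smooth random fields (sums of up to 8
#' low-frequency sinusoids with random orientation and phase, plus a small
#' white-noise component). The fields are orthonormalised over the grid and
#' recombined as `sqrt(correlation) * shared + sqrt(1 - correlation) * own`,
#' so the realised pairwise Pearson correlation between layers equals the
#' requested level exactly (up to the per-layer affine rescaling, which does
#' not affect correlation).
#'
#' @param n_layers Number of layers (>= 2). Defaults to the 17 bioclimatic
#'   layers of [default_bioclim_layers()].
#' @param grid List with elements `nrow`, `ncol`, `xmin`, `ymax`, `cellsize`.
#' @param correlation Target pairwise correlation between layers, in `[0, 1)`.
#' @param trend West-east climatic trend: each layer is offset linearly by
#'   `+- trend / 2` layer standard deviations across the map, emulating the
#'   large-scale geographic climate gradients (e.g. latitudinal temperature
#'   bands) that make distant regions hold genuinely novel climates.
#'   Default 0 (stationary field); note a nonzero trend adds a shared
#'   component, so realised inter-layer correlations exceed `correlation`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param layer_names Optional layer labels (length `n_layers`).
#' @return A [climate_stack()] with no masked cells.
#' @export
#' @examples
#' st <- generate_climate_stack(n_layers = 3, correlation = 0.5, seed = 1)
#' cor(st$values[[1]][, 1], st$values[[2]][, 1])
generate_climate_stack <- function(n_layers = 17L,
                                   grid = list(nrow = 50L, ncol = 50L,
                                               xmin = 0, ymax = 50,
                                               cellsize = 1),
                                   correlation = 0.3,
                                   trend = 0,
                                   seed = 1L,
                                   layer_names = NULL) {
  stopifnot(n_layers >= 2L, correlation >= 0, correlation < 1)
  nr <- as.integer(grid$nrow)
  nc <- as.integer(grid$ncol)
  if (is.na(nr) || is.na(nc) || nr < 2L || nc < 2L) {
    stop("degenerate grid: need at least 2 cells per side")
  }
  if (nr < 20L || nc < 20L) {
    warning("grids smaller than 20 x 20 cells give poorly resolved fields")
  }
  if (is.null(layer_names)) {
    layer_names <- if (n_layers == 17L) default_bioclim_layers() else
      paste0("env", seq_len(n_layers))
  }
  stopifnot(length(layer_names) == n_layers)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  u <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  v <- matrix(rep(seq(0, 1, length.out = nr), times = nc), nr, nc)
  smooth_field <- function() {
    f <- matrix(0, nr, nc)
    for (m in seq_len(8L)) {
      fx <- stats::runif(1, 0.5, 4)
      fy <- stats::runif(1, 0.5, 4)
      sx <- sample(c(-1, 1), 1)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- 1 / m
      f <- f + amp * sin(2 * pi * (sx * fx * u + fy * v) + ph)
    }
    f + stats::rnorm(nr * nc, sd = 0.05 * stats::sd(f))
  }

  # raw fields -> orthonormal basis over the grid, so mixing weights set the
  # realised correlation exactly
  raw <- vapply(seq_len(n_layers + 1L), function(i) as.vector(smooth_field()),
                numeric(nr * nc))
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))
  shared <- q[, 1]
  layers <- vector("list", n_layers)
  trend_field <- as.vector(u) - 0.5
  for (i in seq_len(n_layers)) {
    f <- sqrt(correlation) * shared + sqrt(1 - correlation) * q[, i + 1L]
    f <- f / stats::sd(f) + trend * trend_field
    # arbitrary plausible per-layer location/scale; correlation is unaffected
    layers[[i]] <- matrix(10 * f + 5 * i, nr, nc)
  }
  names(layers) <- layer_names
  climate_stack(layers, xmin = grid$xmin, ymax = grid$ymax,
                cellsize = grid$cellsize)
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read and write single layers as ESRI ASCII grids
#'
#' Plain-text ESRI ASCII grid (`.asc`) files carry the grid geometry in their
#' header and round-trip double-precision values exactly (written with 17
#' significant digits). Nodata cells are written with the `NODATA_value` tag.
#'
#' @param m Numeric matrix (row 1 = north).
#' @param path File path.
#' @param xmin,ymin Western and southern edge coordinates (degrees).
#' @param cellsize Cell size in degrees.
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a list with `values` (matrix, `NA` at nodata), `xmin`, `ymin`,
#'   `cellsize`.
#' @export
write_ascii_grid <- function(m, path, xmin, ymin, cellsize, nodata = -9999) {
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10f", xmin),
    sprintf("yllcorner %.10f", ymin),
    sprintf("cellsize %.10f", cellsize),
    sprintf("NODATA_value %g", nodata)
  )
  vals <- m
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(ln, " +")[[1]][2])
  }
  nc <- as.integer(getv("ncols"))
  nr <- as.integer(getv("nrows"))
  xll <- getv("xllcorner")
  yll <- getv("yllcorner")
  cs <- getv("cellsize")
  nodata <- getv("NODATA_value")
  vals <- t(vapply(lines[7:(6 + nr)],
                   function(l) as.numeric(strsplit(trimws(l), " +")[[1]]),
                   numeric(nc), USE.NAMES = FALSE))
  vals[vals == nodata] <- NA_real_
  list(values = vals, xmin = xll, ymin = yll, cellsize = cs)
}
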