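#' Write a complete synthetic fixture to disk
#'
#' Serialises a climate stack (one ESRI ASCII grid per layer), an occurrence
#' table (CSV with header `species,status,lon,lat`), a polygon map (GeoJSON)
#' and a ground-truth record (JSON) into a directory, together with a
#' manifest listing every file and its MD5 checksum. Grid values are written
#' at full double precision so a round trip reproduces the stack exactly,
#' and re-running with the same inputs reproduces identical checksums.
#'
#' @param out_dir Output directory (created if missing).
#' @param stack A [climate_stack()].
#' @param occurrences Occurrence data.frame (`species,status,lon,lat`).
#' @param polygons A [range_polygons()].
#' @param truth Ground-truth record: a [virtual_species_truth()], a list, or
#'   a data.frame (serialised as JSON).
#' @return The manifest data.frame (columns `file`, `md5`), invisibly also
#'   written to `manifest.csv`. One row per layer plus one each for the
#'   occurrence, polygon and truth files.
#' @export
write_fixture <- function(out_dir, stack, occurrences, polygons, truth) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  .check_occ(occurrences)

  files <- character(0)
  ymin <- stack$ymax - stack$nrow * stack$cellsize
  for (nm in stack$layer_names) {
    f <- file.path(out_dir, paste0(nm, ".asc"))
    m <- stack$values[[nm]]
    m[!stack$mask] <- NA
    write_ascii_grid(m, f, xmin = stack$xmin, ymin = ymin,
                     cellsize = stack$cellsize)
    files <- c(files, f)
  }

  f_occ <- file.path(out_dir, "occurrences.csv")
  utils::write.csv(occurrences[, c("species", "status", "lon", "lat")],
                   f_occ, row.names = FALSE)
  f_poly <- file.path(out_dir, "polygons.geojson")
  write_polygons_geojson(polygons, f_poly)
  f_truth <- file.path(out_dir, "truth.json")
  if (inherits(truth, "virtual_species_truth")) truth <- unclass(truth)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"), f_truth)
  files <- c(files, f_occ, f_poly, f_truth)

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param in_dir Directory containing a `manifest.csv`.
#' @return List with elements `stack` ([climate_stack()]), `occurrences`
#'   (data.frame), `polygons` ([range_polygons()]), `truth` (list or
#'   data.frame).
#' @export
read_fixture <- function(in_dir) {
  manifest <- utils::read.csv(file.path(in_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  asc <- manifest$file[grepl("\\.asc$", manifest$file)]
  layers <- list()
  geom <- NULL
  for (f in asc) {
    g <- read_ascii_grid(file.path(in_dir, f))
    layers[[sub("\\.asc$", "", f)]] <- g$values
    geom <- g
  }
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  vals <- lapply(layers, function(m) {
    m[is.na(m)] <- 0
    m
  })
  stack <- climate_stack(
    vals,
    xmin = geom$xmin,
    ymax = geom$ymin + nrow(vals[[1]]) * geom$cellsize,
    cellsize = geom$cellsize,
    mask = mask
  )
  occ <- utils::read.csv(file.path(in_dir, "occurrences.csv"),
                         stringsAsFactors = FALSE)
  polys <- read_polygons_geojson(file.path(in_dir, "polygons.geojson"))
  truth <- jsonlite::fromJSON(file.path(in_dir, "truth.json"))
  list(stack = stack, occurrences = occ, polygons = polys, truth = truth)
}
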