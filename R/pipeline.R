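#' Pipeline run configuration
#'
#' Collects every tunable parameter of the niche-shift pipeline with the
#' standard defaults: 0.02-degree thinning, minimum 10 occurrences per
#' range, 10 PCA axes, 100 bins on the niche axis, 1000 equivalency
#' permutations, a 10 per cent expansion threshold, and 3 dispersion
#' groups. Every stochastic stage derives its own seed from the master
#' `seed` plus the stage name via [stage_seed()].
#'
#' @param min_dist Thinning nearest-neighbour distance, degrees.
#' @param min_n Minimum occurrences per range.
#' @param n_axes PCA axes retained before the between-class step.
#' @param n_bins Bins on the niche axis.
#' @param n_reps Equivalency permutations.
#' @param equivalency_refit Refit axis/grid per permutation (see
#'   [equivalency_test()]).
#' @param run_equivalency Run the (relatively costly) equivalency test.
#' @param expansion_threshold Low/high expansion boundary, percent.
#' @param presence_quantile Native-presence mass quantile used by
#'   [expansion_pct()]; the pipeline default 0.02 discards about the mass
#'   a Gaussian kernel places beyond 2.3 bandwidths - the tail that
#'   smoothing leaks into bins far from any occurrence - while keeping
#'   genuinely occupied low-density bins.
#' @param correct_availability Apply the availability correction in
#'   [grid_density()].
#' @param background `"hull"` (buffered convex hull of each range) or
#'   `"whole"` (full raster).
#' @param hv_dims,hv_quantile,hv_samples Hypervolume dimensions, mass
#'   quantile, and Monte Carlo samples (`NULL` = `10000 * hv_dims`).
#' @param k_groups Dispersion groups for the k-means step.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(min_dist = 0.02, min_n = 10L, n_axes = 10L,
                       n_bins = 100L, n_reps = 1000L,
                       equivalency_refit = TRUE, run_equivalency = TRUE,
                       expansion_threshold = 10, presence_quantile = 0.02,
                       correct_availability = TRUE, background = "hull",
                       hv_dims = 3L, hv_quantile = 0.95, hv_samples = NULL,
                       k_groups = 3L, seed = 1L) {
  background <- match.arg(background, c("hull", "whole"))
  structure(
    list(min_dist = min_dist, min_n = as.integer(min_n),
         n_axes = as.integer(n_axes), n_bins = as.integer(n_bins),
         n_reps = as.integer(n_reps),
         equivalency_refit = isTRUE(equivalency_refit),
         run_equivalency = isTRUE(run_equivalency),
         expansion_threshold = expansion_threshold,
         presence_quantile = presence_quantile,
         correct_availability = isTRUE(correct_availability),
         background = background,
         hv_dims = as.integer(hv_dims), hv_quantile = hv_quantile,
         hv_samples = hv_samples, k_groups = as.integer(k_groups),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# Internal: axis builder closing over fixed raster backgrounds; refitting
# the axis re-projects the same background cells.
.species_axis_builder <- function(bg_nat, bg_non, config) {
  function(env1, env2) {
    grids <- species_density_grids(env1, env2, bg_nat, bg_non,
                                   n_axes = config$n_axes,
                                   n_bins = config$n_bins,
                                   correct = config$correct_availability)
    list(D = schoener_d(grids$native, grids$nonnative), grids = grids)
  }
}

# Internal: equivalency-test builder. Permuting range labels is only
# coherent against a background common to both groups: keeping each
# range's own availability while the labels permute distorts every mixed
# re-split (occupancy mass lands where that range's availability is near
# zero) and drives the null D far below the observed one.
.species_equivalency_builder <- function(bg_pooled, config) {
  function(env1, env2) {
    grids <- species_density_grids(env1, env2, bg_pooled, bg_pooled,
                                   n_axes = config$n_axes,
                                   n_bins = config$n_bins,
                                   correct = config$correct_availability)
    list(D = schoener_d(grids$native, grids$nonnative))
  }
}

#' Simulate a multi-species virtual cohort
#'
#' Builds one shared synthetic climate stack and polygon map, then one
#' virtual species per row of a (recycled) grid of true niche-shift
#' magnitudes and expansion fractions. Native windows sit in the western
#' half of the extent and non-native windows in the eastern half; window
#' sizes vary across species so the cohort spans a range of polygon
#' richness and Rao entropy. Each species draws its own seed from the
#' master seed, so adding a species never perturbs another's occurrences.
#'
#' @param n_species Number of species (default 30).
#' @param shift_deltas,target_expansions True parameter grids, recycled
#'   across species in lockstep with `expand.grid` order.
#' @param n_native,n_nonnative Occurrence counts (recycled per species).
#' @param seed Master seed.
#' @param stack Optional pre-built [climate_stack()]; default is a 50 x 50
#'   17-layer stack with pairwise correlation 0.3 and a west-east climatic
#'   trend of 3 layer SDs, so the non-native half of the map holds
#'   genuinely novel climates.
#' @param n_poly_x,n_poly_y Polygon tessellation of the stack extent.
#' @param invasive_every Every `invasive_every`-th species is labelled
#'   `invasive`, the rest `alien` (exercise labels for the comparison
#'   layer; invasiveness is an input in this pipeline, not simulated).
#' @param out_dir Optional directory; when given the fixture is written via
#'   [write_fixture()].
#' @return List with `stack`, `occurrences`, `polygons`, `truth`
#'   (data.frame, one row per species incl. `expected_dropped`), `labels`
#'   (species, invasiveness).
#' @export
simulate_cohort <- function(n_species = 30L,
                            shift_deltas = c(0, 1, 2, 3),
                            target_expansions = c(0, 0.25, 0.5, 1),
                            n_native = 200L, n_nonnative = 100L,
                            seed = 1L, stack = NULL,
                            n_poly_x = 10L, n_poly_y = 10L,
                            invasive_every = 6L, out_dir = NULL) {
  if (is.null(stack)) {
    stack <- generate_climate_stack(trend = 3, seed = stage_seed(seed, "stack"))
  }
  ext <- list(xmin = stack$xmin,
              xmax = stack$xmin + stack$ncol * stack$cellsize,
              ymin = stack$ymax - stack$nrow * stack$cellsize,
              ymax = stack$ymax)
  polygons <- generate_polygon_map(n_poly_x, n_poly_y, ext)

  grid <- expand.grid(shift = shift_deltas, expansion = target_expansions)
  n_nat <- rep_len(n_native, n_species)
  n_non <- rep_len(n_nonnative, n_species)
  ids <- sprintf("sp%03d", seq_len(n_species))
  if (anyDuplicated(ids)) stop("conflicting species ids")

  width <- ext$xmax - ext$xmin
  height <- ext$ymax - ext$ymin
  split_x <- ext$xmin + 0.48 * width

  occ_list <- vector("list", n_species)
  truth_rows <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    g <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
    sp_seed <- stage_seed(seed, "species", i)
    old <- .Random.seed_save()
    set.seed(stage_seed(seed, "windows", i))
    # window edge lengths vary across species to spread dispersion
    w_nat <- stats::runif(1, 0.15, 0.9) * (split_x - ext$xmin - 2)
    h_nat <- stats::runif(1, 0.15, 0.9) * (height - 2)
    x_nat <- stats::runif(1, ext$xmin, split_x - 2 - w_nat)
    y_nat <- stats::runif(1, ext$ymin, ext$ymax - h_nat)
    w_non <- stats::runif(1, 0.15, 0.9) * (ext$xmax - split_x - 4)
    h_non <- stats::runif(1, 0.15, 0.9) * (height - 2)
    x_non <- stats::runif(1, split_x + 2, ext$xmax - w_non)
    y_non <- stats::runif(1, ext$ymin, ext$ymax - h_non)
    .Random.seed_restore(old)

    truth <- virtual_species_truth(
      niche_center = 0, niche_breadth = 1,
      shift_delta = g$shift, target_expansion = g$expansion, seed = sp_seed
    )
    occ_list[[i]] <- generate_virtual_species(
      stack, truth,
      native_window = list(xmin = x_nat, xmax = x_nat + w_nat,
                           ymin = y_nat, ymax = y_nat + h_nat),
      nonnative_window = list(xmin = x_non, xmax = x_non + w_non,
                              ymin = y_non, ymax = y_non + h_non),
      n_native = max(n_nat[i], 10L), n_nonnative = max(n_non[i], 10L),
      species = ids[i]
    )
    # species requested below the usable minimum keep only their first
    # records, emulating genuinely data-poor species
    if (n_nat[i] < 10L || n_non[i] < 10L) {
      keep_nat <- which(occ_list[[i]]$status == "native")[seq_len(n_nat[i])]
      keep_non <- which(occ_list[[i]]$status == "nonnative")[seq_len(n_non[i])]
      occ_list[[i]] <- occ_list[[i]][c(keep_nat, keep_non), , drop = FALSE]
    }
    truth_rows[[i]] <- data.frame(
      species = ids[i], shift_delta = g$shift,
      target_expansion = g$expansion,
      n_native = n_nat[i], n_nonnative = n_non[i], seed = sp_seed,
      expected_dropped = (n_nat[i] < 10L || n_non[i] < 10L),
      stringsAsFactors = FALSE
    )
  }
  occurrences <- do.call(rbind, occ_list)
  truth <- do.call(rbind, truth_rows)
  labels <- data.frame(
    species = ids,
    invasiveness = ifelse(seq_len(n_species) %% invasive_every == 0L,
                          "invasive", "alien"),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    write_fixture(out_dir, stack, occurrences, polygons, truth)
  }
  list(stack = stack, occurrences = occurrences, polygons = polygons,
       truth = truth, labels = labels)
}

#' Run the full niche-shift pipeline
#'
#' Executes, in order: occurrence cleaning, per-species discriminant axis
#' and density grids, the three niche metrics (D overlap, expansion,
#' equivalency) with Benjamini-Hochberg correction across species,
#' geographic dispersion metrics and grouping, native hypervolumes in the
#' shared global climate PCA with the two-pass fixed bandwidth, and the
#' group-comparison statistics. Species are processed in sorted id order;
#' the run is a pure function of its inputs and the config (seeds included).
#'
#' @param stack A [climate_stack()].
#' @param occurrences Occurrence data.frame (`species,status,lon,lat`).
#' @param polygons A [range_polygons()].
#' @param labels Optional data.frame (`species`, `invasiveness`); species
#'   without a label are treated as `alien`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for the results bundle
#'   (`species_table.csv`, `tests.json`, `cleaning_report.json`,
#'   `provenance.json`).
#' @return List with `species_table` (one row per surviving species),
#'   `tests` (named list of `test_report`s), `cleaning_report`,
#'   `dropped_species`, `provenance`.
#' @export
run_all <- function(stack, occurrences, polygons, labels = NULL,
                    config = run_config(), out_dir = NULL) {
  stopifnot(inherits(stack, "climate_stack"),
            inherits(polygons, "range_polygons"),
            inherits(config, "run_config"))
  .check_occ(occurrences)

  prep <- preprocess_occurrences(occurrences, stack,
                                 min_dist = config$min_dist,
                                 min_n = config$min_n)
  occ <- prep$occ
  if (nrow(occ) == 0L) stop("no species survived preprocessing")
  species <- sort(unique(occ$species))

  gpca <- fit_global_pca(stack, n_dims = config$hv_dims)
  whole <- config$background == "whole"

  # first pass: per-species native PCA scores for the fixed bandwidth
  native_scores <- lapply(species, function(sp) {
    occ_nat <- occ[occ$species == sp & occ$status == "native", , drop = FALSE]
    project_global(extract_env(occ_nat, stack), gpca)
  })
  names(native_scores) <- species
  b_fixed <- fixed_bandwidth(native_scores)

  rows <- vector("list", length(species))
  p_raw <- rep(NA_real_, length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    occ_sp <- occ[occ$species == sp, , drop = FALSE]
    occ_nat <- occ_sp[occ_sp$status == "native", , drop = FALSE]
    occ_non <- occ_sp[occ_sp$status == "nonnative", , drop = FALSE]
    env_nat <- extract_env(occ_nat, stack)
    env_non <- extract_env(occ_non, stack)
    bg_nat <- range_background(occ_nat, stack, whole_raster = whole)
    bg_non <- range_background(occ_non, stack, whole_raster = whole)

    builder <- .species_axis_builder(bg_nat, bg_non, config)
    obs <- tryCatch(builder(env_nat, env_non), error = function(e) {
      stop("stage niche_space failed for species ", sp, ": ",
           conditionMessage(e))
    })
    D <- obs$D
    E <- expansion_pct(obs$grids$native, obs$grids$nonnative,
                       presence_quantile = config$presence_quantile)
    E_class <- classify_expansion(E, config$expansion_threshold)

    if (config$run_equivalency) {
      eq <- equivalency_test(env_nat, env_non,
                             axis_builder =
                               .species_equivalency_builder(
                                 rbind(bg_nat, bg_non), config),
                             n_reps = config$n_reps,
                             seed = stage_seed(config$seed, "equivalency", i),
                             refit = config$equivalency_refit)
      p_raw[i] <- eq$p
    }

    op_all <- occupied_polygons(occ_sp, polygons)
    op_nat <- occupied_polygons(occ_sp, polygons, status = "native")
    cen_all <- polygons$centroids[polygons$ids %in% op_all$ids, , drop = FALSE]
    cen_nat <- polygons$centroids[polygons$ids %in% op_nat$ids, , drop = FALSE]
    hv <- gaussian_hypervolume(
      native_scores[[sp]], b = b_fixed, q = config$hv_quantile,
      n_samples = if (is.null(config$hv_samples)) NULL else config$hv_samples,
      seed = stage_seed(config$seed, "hypervolume", i), species_id = sp
    )

    rows[[i]] <- data.frame(
      species_id = sp,
      n_native = nrow(env_nat), n_nonnative = nrow(env_non),
      D = D, expansion_pct = E, expansion_class = E_class,
      p_equiv = p_raw[i],
      richness = op_all$richness,
      rao_native = rao_entropy(cen_nat),
      rao_total = rao_entropy(cen_all),
      volume = hv$volume,
      stringsAsFactors = FALSE
    )
  }
  st <- do.call(rbind, rows)
  st$p_equiv_adj <- if (config$run_equivalency) bh_adjust(st$p_equiv) else NA_real_
  st$group <- tryCatch(
    classify_dispersion(data.frame(richness = st$richness,
                                   rao_total = st$rao_total),
                        k = config$k_groups,
                        seed = stage_seed(config$seed, "kmeans")),
    error = function(e) rep(NA_character_, nrow(st))
  )
  if (is.null(labels)) {
    st$invasiveness <- "alien"
  } else {
    st$invasiveness <- labels$invasiveness[match(st$species_id, labels$species)]
    st$invasiveness[is.na(st$invasiveness)] <- "alien"
  }

  tests <- .comparison_battery(st)

  provenance <- list(
    package_version = as.character(utils::packageVersion("nicheshift")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = .config_hash(config),
    n_species_in = length(unique(occurrences$species)),
    n_species_out = nrow(st)
  )

  out <- list(species_table = st, tests = tests,
              cleaning_report = prep$report,
              dropped_species = prep$dropped_species,
              provenance = provenance, config = config)
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

# Internal: the group-comparison battery mirroring the study design; each
# test is attempted and omitted when its preconditions fail (e.g. a single
# group present).
.comparison_battery <- function(st) {
  try_test <- function(expr) tryCatch(expr, error = function(e) NULL)
  tests <- list(
    kw_D_invasiveness = try_test(kruskal_wallis(st$D, st$invasiveness)),
    chisq_expansion_invasiveness = try_test(
      chi_squared_counts(table(st$expansion_class, st$invasiveness))),
    kw_D_dispersion = try_test(kruskal_wallis(st$D, st$group)),
    dunn_D_dispersion = try_test(dunn_posthoc(st$D, st$group)),
    chisq_expansion_dispersion = try_test(
      chi_squared_counts(table(st$expansion_class, st$group))),
    kw_rao_expansion = try_test(
      kruskal_wallis(st$rao_native, st$expansion_class)),
    kw_volume_expansion = try_test(
      kruskal_wallis(st$volume, st$expansion_class)),
    kendall_D_rao = try_test(kendall_tau(st$D, st$rao_native)),
    kendall_D_volume = try_test(kendall_tau(st$D, st$volume)),
    occurrence_sensitivity = try_test(occurrence_sensitivity(st))
  )
  tests[!vapply(tests, is.null, logical(1))]
}

# Internal: stable hash of the config for provenance.
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), f)
  unname(tools::md5sum(f))
}

# Internal: serialise a results bundle.
.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$species_table,
                   file.path(out_dir, "species_table.csv"), row.names = FALSE)
  to_plain <- function(x) {
    if (inherits(x, "test_report")) {
      x <- unclass(x)
      x$pairwise <- if (!is.null(x$pairwise)) x$pairwise else NULL
    } else if (is.list(x)) {
      x <- lapply(x, to_plain)
    }
    x
  }
  writeLines(jsonlite::toJSON(to_plain(res$tests), auto_unbox = TRUE,
                              digits = NA, dataframe = "rows", null = "null",
                              pretty = TRUE),
             file.path(out_dir, "tests.json"))
  writeLines(jsonlite::toJSON(res$cleaning_report, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "cleaning_report.json"))
  writeLines(jsonlite::toJSON(res$provenance, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(out_dir, "provenance.json"))
  invisible(out_dir)
}
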