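test_that("climate stacks are well-formed, deterministic, and hit the requested correlation", {
  st <- generate_climate_stack(n_layers = 17, correlation = 0.3, seed = 1)
  expect_s3_class(st, "climate_stack")
  expect_length(st$layer_names, 17)
  expect_identical(st$layer_names, default_bioclim_layers())
  expect_true(all(st$mask))
  expect_equal(st$nrow, 50L)

  st2 <- generate_climate_stack(n_layers = 17, correlation = 0.3, seed = 1)
  expect_identical(st$values, st2$values)

  st0 <- generate_climate_stack(n_layers = 17, correlation = 0, seed = 2)
  cc <- stats::cor(stack_cell_env(st0))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.25)

  st3 <- generate_climate_stack(n_layers = 5, correlation = 0.6, seed = 3)
  cc3 <- stats::cor(stack_cell_env(st3))
  expect_equal(mean(cc3[upper.tri(cc3)]), 0.6, tolerance = 1e-6)

  expect_error(generate_climate_stack(grid = list(nrow = 1, ncol = 40,
                                                  xmin = 0, ymax = 1,
                                                  cellsize = 1)),
               "degenerate")
})

test_that("virtual species have the requested composition and are seed-deterministic", {
  w <- small_world()
  tr <- virtual_species_truth(seed = 7)
  occ <- generate_virtual_species(w$stack, tr, w$nat_w, w$non_w,
                                  n_native = 200, n_nonnative = 100)
  expect_equal(nrow(occ), 300)
  expect_equal(as.integer(table(occ$status)[c("native", "nonnative")]),
               c(200L, 100L))
  occ2 <- generate_virtual_species(w$stack, tr, w$nat_w, w$non_w,
                                   n_native = 200, n_nonnative = 100)
  expect_identical(occ, occ2)

  # environmental values at occurrence points stay within the layer ranges
  env <- extract_env(occ, w$stack)
  for (nm in w$stack$layer_names) {
    expect_gte(min(env[, nm]), min(w$stack$values[[nm]]))
    expect_lte(max(env[, nm]), max(w$stack$values[[nm]]))
  }

  expect_error(generate_virtual_species(
    w$stack, tr, w$nat_w, list(xmin = 5, xmax = 20, ymin = 2, ymax = 20),
    200, 100), "disjoint")
})

test_that("target_expansion = 1 forces every non-native point outside the native envelope", {
  w <- small_world()
  tr <- virtual_species_truth(target_expansion = 1, seed = 11)
  occ <- generate_virtual_species(w$stack, tr, w$nat_w, w$non_w, 100, 60)
  env <- extract_env(occ, w$stack)
  nat <- env[occ$status == "native", , drop = FALSE]
  non <- env[occ$status == "nonnative", , drop = FALSE]
  lo <- apply(nat, 2, min)
  hi <- apply(nat, 2, max)
  outside <- rowSums(sweep(non, 2, lo, "<") | sweep(non, 2, hi, ">")) > 0
  expect_true(all(outside))
})

test_that("zero shift and zero expansion give closely matched environment scores", {
  # on a stationary landscape (no climatic trend) both windows offer the
  # same climates, so an unshifted species realises matching niches; with
  # a trend, availability alone can displace the realised sample
  st <- generate_climate_stack(
    n_layers = 6,
    grid = list(nrow = 30L, ncol = 30L, xmin = 0, ymax = 30, cellsize = 1),
    correlation = 0.3, trend = 0, seed = 8
  )
  w <- small_world()
  tr <- virtual_species_truth(shift_delta = 0, target_expansion = 0, seed = 5)
  occ <- generate_virtual_species(st, tr, w$nat_w, w$non_w, 200, 100)
  env <- extract_env(occ, st)
  z <- scale(env)
  s <- as.numeric(z %*% stats::prcomp(z, center = FALSE)$rotation[, 1])
  gap <- abs(mean(s[occ$status == "native"]) - mean(s[occ$status == "nonnative"]))
  expect_lt(gap, 0.5 * stats::sd(s))
})

test_that("polygon tessellations have exact centroid geometry and unique ids", {
  p1 <- generate_polygon_map(1, 1, list(xmin = 0, xmax = 1, ymin = 0, ymax = 1))
  expect_length(p1$ids, 1)
  expect_equal(unname(p1$centroids[1, ]), c(0.5, 0.5))

  p2 <- generate_polygon_map(2, 1, list(xmin = 0, xmax = 2, ymin = 0, ymax = 1))
  expect_equal(unname(p2$centroids[, "lon"]), c(0.5, 1.5))
  expect_equal(unname(p2$centroids[, "lat"]), c(0.5, 0.5))
  expect_equal(sqrt(sum((p2$centroids[1, ] - p2$centroids[2, ])^2)), 1)

  p9 <- generate_polygon_map(3, 3, list(xmin = -10, xmax = 20, ymin = 0, ymax = 30))
  expect_length(unique(p9$ids), 9)

  expect_error(generate_polygon_map(2, 2, list(xmin = 0, xmax = 0,
                                               ymin = 0, ymax = 1)),
               "empty extent")
})

test_that("fixtures round-trip exactly with a complete, reproducible manifest", {
  w <- small_world()
  tr <- virtual_species_truth(seed = 3)
  occ <- generate_virtual_species(w$stack, tr, w$nat_w, w$non_w, 30, 20)
  dir <- withr::local_tempdir()
  man <- write_fixture(dir, w$stack, occ, w$polygons, tr)
  expect_equal(nrow(man), length(w$stack$layer_names) + 3L)

  back <- read_fixture(dir)
  expect_identical(back$stack$values, w$stack$values)
  expect_equal(back$occurrences$lon, occ$lon)
  expect_identical(back$polygons$ids, w$polygons$ids)
  expect_equal(back$polygons$centroids, w$polygons$centroids)

  man2 <- write_fixture(dir, w$stack, occ, w$polygons, tr)
  expect_identical(man$md5, man2$md5)
})
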