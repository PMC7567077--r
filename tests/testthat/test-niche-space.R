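test_that("the discriminant axis has unit norm and separates distinct clouds", {
  cl <- gaussian_clouds(n1 = 80, n2 = 80, d = 3, sep = 4, seed = 2)
  ax <- fit_species_axis(cl$a, cl$b, n_axes = 3)
  expect_equal(sum(ax$bca^2), 1)
  sa <- project_axis(cl$a, ax)
  sb <- project_axis(cl$b, ax)
  # well-separated clouds: non-overlapping interquartile ranges
  expect_lt(stats::quantile(sa, 0.75), stats::quantile(sb, 0.25))
  # sign convention: native centroid projects below the non-native one
  expect_lt(mean(sa), mean(sb))
})

test_that("identical classes fall back to PC1 with a warning", {
  cl <- gaussian_clouds(n1 = 40, n2 = 40, d = 4, seed = 3)
  expect_warning(ax <- fit_species_axis(cl$a, cl$a, n_axes = 4),
                 "identical class centroids")
  expect_equal(ax$bca, c(1, 0, 0, 0))
})

test_that("zero-variance variables are dropped with a warning", {
  cl <- gaussian_clouds(n1 = 30, n2 = 30, d = 3, sep = 1, seed = 4)
  a <- cbind(cl$a, flat = 1)
  b <- cbind(cl$b, flat = 1)
  expect_warning(ax <- fit_species_axis(a, b), "zero-variance")
  expect_false("flat" %in% ax$vars)
})

test_that("projection is centred, deterministic, and unit-scaled along the axis", {
  cl <- gaussian_clouds(n1 = 50, n2 = 50, d = 4, sep = 2, seed = 5)
  ax <- fit_species_axis(cl$a, cl$b, n_axes = 4)
  pooled <- rbind(cl$a, cl$b)
  mean_row <- matrix(colMeans(pooled), 1,
                     dimnames = list(NULL, colnames(pooled)))
  expect_equal(as.numeric(project_axis(mean_row, ax)), 0, tolerance = 1e-10)
  expect_identical(project_axis(cl$a, ax), project_axis(cl$a, ax))

  # a point 1 SD along the bca direction in standardised space scores 1
  v_std <- as.numeric(ax$loadings %*% ax$bca)   # direction in variable space
  x_raw <- matrix(ax$mean + ax$sd * v_std, 1,
                  dimnames = list(NULL, ax$vars))
  expect_equal(as.numeric(project_axis(x_raw, ax)), 1, tolerance = 1e-8)

  expect_error(project_axis(cl$a[, 1:2], ax), "lacks")
})

test_that("density grids are normalised, availability-corrected, and share bins", {
  set.seed(6)
  bg <- rnorm(1000)
  occ <- bg                       # occurrences identical to the background
  gd <- grid_density(occ, bg)
  expect_equal(sum(gd$o), 1, tolerance = 1e-9)
  expect_equal(sum(gd$e), 1, tolerance = 1e-9)
  expect_equal(sum(gd$z), 1, tolerance = 1e-9)
  expect_true(all(gd$z[gd$e <= 1e-12] == 0))
  occupied <- gd$z[gd$z > 0]
  expect_lt(max(occupied) / min(occupied), 3)

  # occurrences crammed into one far corner of a uniform background
  set.seed(7)
  bg2 <- runif(2000, 0, 10)
  occ2 <- runif(300, 9.6, 10)
  gd2 <- grid_density(occ2, bg2)
  ord <- order(gd2$z, decreasing = TRUE)
  n95 <- which(cumsum(gd2$z[ord]) >= 0.95)[1]
  expect_lt(n95, 20)

  expect_error(grid_density(rep(1, 5), bg), "distinct")
})

test_that("shared bounds give a common grid and duplication leaves z unchanged", {
  set.seed(8)
  s1 <- rnorm(100)
  s2 <- rnorm(80, 2)
  bg <- c(rnorm(300), rnorm(300, 2))
  bounds <- range(c(s1, s2, bg))
  g1 <- grid_density(s1, bg, bounds = bounds)
  g2 <- grid_density(s2, bg, bounds = bounds)
  expect_identical(g1$edges, g2$edges)

  g1dup <- grid_density(rep(s1, 2), bg, bounds = bounds,
                        bandwidth = g1$bw_occ)
  expect_equal(g1dup$z, g1$z, tolerance = 1e-12)
})

test_that("doubling availability in a region halves corrected occupancy there", {
  set.seed(9)
  occ <- runif(400, 0, 10)
  bg <- runif(4000, 0, 10)
  extra <- bg[bg > 5]             # duplicate availability in the upper half
  g1 <- grid_density(occ, bg, bounds = c(0, 10), bandwidth = 0.4)
  g2 <- grid_density(occ, c(bg, extra), bounds = c(0, 10), bandwidth = 0.4)
  mid <- g1$mid
  lower <- mid > 1 & mid < 4      # away from edges and the step
  upper <- mid > 6 & mid < 9
  ratio_low <- mean(g1$z[lower] / g2$z[lower])
  ratio_up <- mean(g1$z[upper] / g2$z[upper])
  expect_equal(ratio_up / ratio_low, 2, tolerance = 0.2)
})

test_that("range backgrounds cover the occupied hull plus a buffer", {
  w <- small_world()
  occ <- data.frame(species = "a", status = "native",
                    lon = c(3, 9, 3, 9, 6), lat = c(5, 5, 12, 12, 8))
  bg <- range_background(occ, w$stack)
  # hull spans 6 x 7 cells; with a 1-cell buffer expect roughly 8 x 9
  expect_gte(nrow(bg), 42)
  expect_lte(nrow(bg), 100)
  whole <- range_background(occ, w$stack, whole_raster = TRUE)
  expect_equal(nrow(whole), w$stack$nrow * w$stack$ncol)
})

test_that("axis and grid serialisation round-trip their numbers", {
  cl <- gaussian_clouds(n1 = 40, n2 = 40, d = 3, sep = 2, seed = 10)
  ax <- fit_species_axis(cl$a, cl$b, n_axes = 3)
  f <- withr::local_tempfile(fileext = ".json")
  axis_to_json(ax, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$bca, unname(ax$bca), tolerance = 1e-12)
  expect_equal(back$mean, unname(ax$mean), tolerance = 1e-12)

  s <- project_axis(cl$a, ax)
  gd <- grid_density(s, s, n_bins = 20)
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- grid_density_table(gd, csv)
  expect_identical(names(tab), c("bin_mid", "o", "e", "z"))
  expect_equal(utils::read.csv(csv)$z, gd$z, tolerance = 1e-12)
})

test_that("the 2-D density variant agrees with the 1-D axis on direction of change", {
  tr0 <- virtual_species_truth(shift_delta = 0, seed = 61)
  tr3 <- virtual_species_truth(shift_delta = 3, seed = 61)
  d_for <- function(tr) {
    sp <- small_species(tr)
    pca <- pooled_pc12(sp$env_nat, sp$env_non)
    gn <- grid_density_2d(sp$env_nat, sp$bg_nat, pca, n_bins = 50,
                          bounds = rbind(c(-6, 6), c(-6, 6)))
    go <- grid_density_2d(sp$env_non, sp$bg_non, pca, n_bins = 50,
                          bounds = rbind(c(-6, 6), c(-6, 6)))
    schoener_d(gn$z, go$z)
  }
  expect_gt(d_for(tr0), d_for(tr3))
})
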