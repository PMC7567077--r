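test_that("nearest-neighbour thinning drops close points and keeps the rest in order", {
  occ <- data.frame(species = "a", status = "native",
                    lon = c(0, 0, 0), lat = c(0, 0.01, 1))
  out <- thin_nnd(occ, min_dist = 0.02)
  expect_equal(out$lat, c(0, 1))

  one <- occ[1, ]
  expect_identical(thin_nnd(one), one)

  spread <- data.frame(species = "a", status = "native",
                       lon = c(0, 0.5, 0.1), lat = c(0, 0, 0.5))
  expect_identical(thin_nnd(spread, 0.02), spread)

  expect_error(thin_nnd(occ, min_dist = -1), "non-negative")
})

test_that("thinning is idempotent and guarantees the minimum distance on random inputs", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    occ <- data.frame(
      species = sample(c("a", "b"), n, replace = TRUE),
      status = sample(c("native", "nonnative"), n, replace = TRUE),
      lon = runif(n, 0, 0.3), lat = runif(n, 0, 0.3)
    )
    t1 <- thin_nnd(occ, 0.02)
    expect_identical(thin_nnd(t1, 0.02), t1)
    expect_lte(nrow(t1), nrow(occ))
    for (g in unique(paste(t1$species, t1$status))) {
      sub <- t1[paste(t1$species, t1$status) == g, ]
      if (nrow(sub) > 1) {
        d <- as.matrix(dist(cbind(sub$lon, sub$lat)))
        diag(d) <- Inf
        expect_gt(min(d), 0.02)
      }
    }
  }
})

test_that("per-cell deduplication keeps one record per species x status x cell", {
  w <- small_world()
  occ <- data.frame(
    species = c("a", "a", "a", "a"),
    status = c("native", "native", "nonnative", "native"),
    lon = c(5.2, 5.4, 5.2, 9.7),  # first three in cell (col 6)
    lat = c(10.2, 10.4, 10.2, 20.1)
  )
  out <- dedupe_grid_cells(occ, w$stack)
  # two natives share a cell -> one survives; nonnative in same cell kept
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$status == "nonnative"), 1)

  spread <- data.frame(species = "a", status = "native",
                       lon = c(1.5, 3.5, 5.5, 7.5, 9.5), lat = rep(10.5, 5))
  expect_equal(nrow(dedupe_grid_cells(spread, w$stack)), 5)

  outside <- rbind(spread,
                   data.frame(species = "a", status = "native",
                              lon = 100, lat = 10.5))
  expect_message(res <- dedupe_grid_cells(outside, w$stack), "outside")
  expect_equal(attr(res, "dropped_outside"), 1L)
})

test_that("the minimum-occurrence filter applies the >= 10 per-range rule", {
  mk <- function(sp, status, n) {
    data.frame(species = sp, status = status,
               lon = seq_len(n) * 0.1, lat = seq_len(n) * 0.1)
  }
  occ <- rbind(mk("few", "native", 9), mk("few", "nonnative", 50),
               mk("ok", "native", 10), mk("ok", "nonnative", 10))
  res <- filter_min_occurrences(occ, 10)
  expect_identical(res$dropped, "few")
  expect_identical(unique(res$occ$species), "ok")

  empty <- occ[0, ]
  res0 <- filter_min_occurrences(empty, 10)
  expect_equal(nrow(res0$occ), 0)
  expect_length(res0$dropped, 0)
})

test_that("environmental extraction uses the half-open containing cell", {
  w <- small_world()
  st <- w$stack
  # cell centre of row 3, col 5
  ctr <- data.frame(species = "a", status = "native",
                    lon = st$xmin + 4.5 * st$cellsize,
                    lat = st$ymax - 2.5 * st$cellsize)
  env <- extract_env(ctr, st)
  for (nm in st$layer_names) {
    expect_identical(unname(env[1, nm]), st$values[[nm]][3, 5])
  }
  # a point on the shared edge of cols 4/5 belongs to col 5 ([x, x+dx))
  edge <- data.frame(species = "a", status = "native",
                     lon = st$xmin + 4 * st$cellsize,
                     lat = st$ymax - 2.5 * st$cellsize)
  expect_identical(unname(extract_env(edge, st)[1, 1]), st$values[[1]][3, 5])

  # constant layer propagates to a constant column
  st2 <- st
  st2$values[[1]][] <- 7
  occ <- data.frame(species = "a", status = "native",
                    lon = c(3.3, 8.8, 14.1), lat = c(4.4, 12.2, 25.5))
  expect_true(all(extract_env(occ, st2)[, 1] == 7))
})

test_that("the cleaning chain reports every dropped record exactly once", {
  w <- small_world()
  tr <- virtual_species_truth(seed = 21)
  occ <- generate_virtual_species(w$stack, tr, w$nat_w, w$non_w, 60, 40)
  res <- suppressMessages(preprocess_occurrences(occ, w$stack))
  rep <- res$report
  expect_equal(rep$input - rep$excluded_manual - rep$dropped_thinning -
                 rep$dropped_outside_extent - rep$dropped_cell_duplicates -
                 rep$dropped_min_occurrences,
               rep$output)
  expect_equal(nrow(res$occ), rep$output)
})
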