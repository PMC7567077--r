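test_that("the global climate PCA is ordered, centred, and merges duplicate layers", {
  w <- small_world()
  pca <- fit_global_pca(w$stack, n_dims = 3)
  expect_true(all(diff(pca$explained_var) <= 1e-12))
  # the global cell mean projects to the origin
  env <- stack_cell_env(w$stack)
  mean_row <- matrix(colMeans(env), 1, dimnames = list(NULL, colnames(env)))
  expect_equal(as.numeric(project_global(mean_row, pca)), rep(0, 3),
               tolerance = 1e-10)

  # two perfectly correlated layers: one axis carries >= 99% of variance
  m <- w$stack$values[[1]]
  dup <- climate_stack(list(a = m, b = 2 * m + 5), xmin = 0, ymax = 30,
                       cellsize = 1)
  p2 <- fit_global_pca(dup, n_dims = 2)
  expect_gte(p2$explained_var[1], 0.99)
})

test_that("Silverman bandwidths follow the 1.06 sd n^(-1/5) rule", {
  set.seed(1)
  x <- matrix(rnorm(200), 100, 2)
  b <- silverman_bandwidth(x)
  expect_equal(b, 1.06 * apply(x, 2, sd) * 100^(-0.2), tolerance = 1e-12)
  expect_equal(unname(silverman_bandwidth(2 * x) / b), c(2, 2),
               tolerance = 1e-12)
  expect_warning(bz <- silverman_bandwidth(matrix(c(1, 1, 2, 2), 2)),
                 "zero spread")
  expect_true(all(bz > 0))
})

test_that("the fixed bandwidth is the max over species of per-axis maxima", {
  s1 <- diag(2)[rep(1:2, 10), ] * 3      # crafted spreads
  s2 <- diag(2)[rep(1:2, 10), ] * 1
  expect_equal(fixed_bandwidth(list(s1)), max(silverman_bandwidth(s1)))
  b12 <- fixed_bandwidth(list(s1, s2))
  expect_gte(b12, fixed_bandwidth(list(s2)))
  expect_equal(b12, max(silverman_bandwidth(s1), silverman_bandwidth(s2)))
})

test_that("hypervolumes are seed-deterministic, nested in q, and scale as c^d", {
  set.seed(2)
  x <- matrix(rnorm(600), 300, 2)
  b <- 0.3
  h1 <- gaussian_hypervolume(x, b, q = 0.9, n_samples = 5000, seed = 5)
  h2 <- gaussian_hypervolume(x, b, q = 0.9, n_samples = 5000, seed = 5)
  expect_identical(h1$volume, h2$volume)

  h95 <- gaussian_hypervolume(x, b, q = 0.95, n_samples = 5000, seed = 5)
  h99 <- gaussian_hypervolume(x, b, q = 0.99, n_samples = 5000, seed = 5)
  expect_lte(h1$volume, h95$volume)
  expect_lte(h95$volume, h99$volume)

  hs <- gaussian_hypervolume(2 * x, 2 * b, q = 0.9, n_samples = 5000, seed = 5)
  expect_equal(hs$volume / h1$volume, 4, tolerance = 1e-9)

  expect_error(gaussian_hypervolume(x, b, q = 1.2), "q must")
  expect_error(gaussian_hypervolume(x, b, n_samples = 10), "n_samples")
})

test_that("hypervolumes are rotation-invariant and roughly additive over clusters", {
  set.seed(3)
  x <- matrix(rnorm(800), 400, 2) %*% diag(c(2, 0.5))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  b <- 0.3
  h <- gaussian_hypervolume(x, b, q = 0.9, n_samples = 20000, seed = 6)
  hr <- gaussian_hypervolume(x %*% rot, b, q = 0.9, n_samples = 20000, seed = 7)
  expect_equal(hr$volume / h$volume, 1, tolerance = 0.05)

  # two well-separated clusters ~ sum of the parts
  a <- matrix(rnorm(400), 200, 2)
  bb <- matrix(rnorm(400), 200, 2) + 25
  ha <- gaussian_hypervolume(a, b, q = 0.9, n_samples = 20000, seed = 8)
  hb <- gaussian_hypervolume(bb, b, q = 0.9, n_samples = 20000, seed = 9)
  hab <- gaussian_hypervolume(rbind(a, bb), b, q = 0.9, n_samples = 40000,
                              seed = 10)
  expect_equal(hab$volume / (ha$volume + hb$volume), 1, tolerance = 0.1)
})

test_that("larger data spread gives larger volume on paired seeds", {
  set.seed(4)
  x <- matrix(rnorm(500), 250, 2)
  b <- 0.3
  v1 <- gaussian_hypervolume(x, b, q = 0.9, n_samples = 5000, seed = 11)$volume
  v2 <- gaussian_hypervolume(1.5 * x, b, q = 0.9, n_samples = 5000,
                             seed = 11)$volume
  expect_gt(v2, v1)
})
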