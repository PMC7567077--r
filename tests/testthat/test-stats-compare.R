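test_that("Kruskal-Wallis matches the brute-force rank oracle", {
  v <- c(1, 2, 3, 10, 20, 30)
  g <- rep(c("a", "b"), each = 3)
  rep1 <- kruskal_wallis(v, g)
  expect_equal(rep1$statistic, oracle_kruskal_h(v, g), tolerance = 1e-9)
  expect_equal(rep1$df, 1)

  set.seed(1)
  for (i in 1:15) {
    n <- sample(6:10, 1)
    vals <- sample(1:5, n, replace = TRUE)      # ties on purpose
    grp <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || length(unique(vals)) < 2) next
    expect_equal(kruskal_wallis(vals, grp)$statistic,
                 oracle_kruskal_h(vals, grp), tolerance = 1e-9)
  }

  tied <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 non-empty groups")
})

test_that("the chi-squared statistic matches the margin oracle", {
  t1 <- matrix(c(10, 10, 10, 10), 2)
  r1 <- chi_squared_counts(t1)
  expect_equal(r1$statistic, 0)

  t2 <- matrix(c(30, 10, 10, 30), 2)
  r2 <- chi_squared_counts(t2)
  expect_equal(r2$statistic, oracle_chisq(t2), tolerance = 1e-9)
  expect_equal(r2$statistic, 20, tolerance = 1e-9) # hand value for this table

  t3 <- matrix(c(5, 3, 2, 8, 1, 7), 2)
  expect_equal(chi_squared_counts(t3)$df, 2)
  expect_equal(chi_squared_counts(t3)$statistic, oracle_chisq(t3),
               tolerance = 1e-9)

  expect_error(chi_squared_counts(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("Dunn pairwise z and adjustments match the oracle and BH ordering", {
  set.seed(2)
  v <- c(rnorm(10), rnorm(10), rnorm(10) + 5)
  g <- rep(c("a", "b", "c"), each = 10)
  rep1 <- dunn_posthoc(v, g)
  tab <- rep1$pairwise
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$z[i], oracle_dunn_z(v, g, tab$group1[i], tab$group2[i]),
                 tolerance = 1e-9)
  }
  expect_true(all(tab$p_adj >= tab$p))
  expect_equal(tab$p_adj, oracle_bh(tab$p), tolerance = 1e-12)

  # two identical groups plus one far-shifted: cross pairs significant
  ab <- tab[tab$group1 == "a" & tab$group2 == "b", ]
  expect_gt(ab$p_adj, 0.05)
  expect_lt(max(tab$p_adj[tab$group2 == "c" | tab$group1 == "c"]), 0.05)

  expect_error(dunn_posthoc(v[1:20], g[1:20]), "3 groups")
})

test_that("Kendall tau-b matches the pair-enumeration oracle", {
  expect_equal(kendall_tau(1:5, (1:5) * 2)$statistic, 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  r <- kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$statistic, 2 / 3, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$statistic, oracle_tau_b(x, y),
                 tolerance = 1e-9)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("the occurrence-count sensitivity block behaves across regimes", {
  # forced concordance
  tab <- data.frame(D = 1:20 / 20, n_native = 1:20,
                    expansion_class = rep(c("low", "high"), 10))
  res <- occurrence_sensitivity(tab)
  expect_true(res$computable)
  expect_equal(res$tau_report$statistic, 1)

  # single species: flagged not computable
  expect_false(occurrence_sensitivity(tab[1, , drop = FALSE])$computable)

  # independent D and n: tau near zero most of the time
  set.seed(4)
  hits <- replicate(40, {
    t2 <- data.frame(D = runif(25), n_native = sample(20:400, 25),
                     expansion_class = sample(c("low", "high"), 25, TRUE))
    occurrence_sensitivity(t2)$tau_report$p > 0.05
  })
  expect_gte(mean(hits), 0.8)
})
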