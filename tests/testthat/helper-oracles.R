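# Independent brute-force oracles for the rank/margin/pair statistics.
# Written from the textbook formulas with explicit loops; deliberately
# separate from the package implementations.

oracle_kruskal_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    h <- h + sum(idx) * mean(r[idx])^2
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  x2 <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / total
      x2 <- x2 + (tab[i, j] - e)^2 / e
    }
  }
  x2
}

oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx != 0 && dy != 0) {
        if (dx == dy) conc <- conc + 1 else disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - sum_tie_pairs(x)) * (n0 - sum_tie_pairs(y)))
}

# pairs tied in a vector (both members equal)
sum_tie_pairs <- function(v) {
  tt <- table(v)
  sum(tt * (tt - 1) / 2)
}

oracle_dunn_z <- function(values, groups, g1, g2) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  s2 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  i1 <- groups == g1
  i2 <- groups == g2
  (mean(r[i1]) - mean(r[i2])) /
    sqrt(s2 * (1 / sum(i1) + 1 / sum(i2)))
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  prev <- 1
  for (k in seq_along(ord)) {
    i <- ord[k]
    rank_i <- m - k + 1
    prev <- min(prev, p[i] * m / rank_i)
    adj[i] <- prev
  }
  pmin(adj, 1)
}
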