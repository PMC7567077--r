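# Internal: assemble a test report.
.test_report <- function(method, statistic, df, p, n, pairwise = NULL) {
  structure(
    list(method = method, statistic = unname(statistic), df = unname(df),
         p = unname(p), n = n, pairwise = pairwise),
    class = "test_report"
  )
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic,
              if (is.null(x$df) || is.na(x$df)) "NA" else format(x$df),
              x$p))
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic against a chi-squared reference with
#' `groups - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#' When every observation is identical the statistic is 0 and p = 1 by
#' convention.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return A `test_report`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0L)) stop("empty group")
  sizes <- as.list(table(groups))
  if (length(unique(values)) == 1L) {
    return(.test_report("Kruskal-Wallis rank sum test", 0,
                        nlevels(groups) - 1L, 1, sizes))
  }
  kt <- stats::kruskal.test(values, groups)
  .test_report("Kruskal-Wallis rank sum test", kt$statistic,
               kt$parameter, kt$p.value, sizes)
}

#' Pearson chi-squared test on a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the row/column
#' margins and `df = (r - 1)(c - 1)`; no continuity correction (delegates to
#' [stats::chisq.test()]).
#'
#' @param counts `r x c` matrix of non-negative counts with positive
#'   margins.
#' @return A `test_report`.
#' @export
chi_squared_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  .test_report("Pearson's chi-squared test", ct$statistic, ct$parameter,
               ct$p.value, list(total = sum(counts)))
}

#' Dunn post-hoc test with multiplicity adjustment
#'
#' Pairwise z statistics on the pooled ranks with tie correction,
#' two-sided normal p-values, adjusted by Benjamini-Hochberg across all
#' pairs. The usual follow-up to a significant Kruskal-Wallis test with
#' three or more groups.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 3 non-empty groups).
#' @return A `test_report` whose `pairwise` field is a data.frame with
#'   columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 3L) stop("need at least 3 groups (use kruskal_wallis for 2)")
  n <- length(values)
  r <- rank(values)
  nv <- tabulate(groups)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  tab <- data.frame(
    group1 = levels(groups)[pairs[1, ]],
    group2 = levels(groups)[pairs[2, ]],
    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    se <- sqrt(s2 * (1 / nv[a] + 1 / nv[b]))
    tab$z[i] <- (rbar[a] - rbar[b]) / se
    tab$p[i] <- 2 * stats::pnorm(-abs(tab$z[i]))
  }
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  .test_report("Dunn post-hoc test (BH adjusted)", NA_real_, NA_real_,
               min(tab$p_adj), as.list(table(groups)), pairwise = tab)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau-b with a two-sided p-value (delegates to
#' [stats::cor.test()]; exact enumeration for small untied samples, normal
#' approximation otherwise).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A `test_report`; the `statistic` field holds tau.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant vector: tau undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  .test_report("Kendall rank correlation (tau-b)", ct$estimate, NA_real_,
               ct$p.value, list(n = length(x)))
}

#' Sensitivity of the niche metrics to occurrence counts
#'
#' Quality-control block: Kendall correlation between D overlap and the
#' number of native occurrences, and a Kruskal-Wallis comparison of native
#' occurrence counts across expansion classes. A strong association would
#' indicate that sample size, not biology, drives the metrics.
#'
#' @param species_table data.frame with columns `D`, `n_native`,
#'   `expansion_class`.
#' @return List with `computable` flag and (when computable) `tau_report`
#'   and `kw_report`.
#' @export
occurrence_sensitivity <- function(species_table) {
  stopifnot(is.data.frame(species_table), nrow(species_table) >= 1L)
  need <- c("D", "n_native", "expansion_class")
  stopifnot(all(need %in% names(species_table)))
  if (nrow(species_table) < 3L) {
    return(list(computable = FALSE,
                reason = "fewer than 3 species"))
  }
  tau <- tryCatch(kendall_tau(species_table$D, species_table$n_native),
                  error = function(e) NULL)
  kw <- if (length(unique(species_table$expansion_class)) >= 2L) {
    kruskal_wallis(species_table$n_native, species_table$expansion_class)
  } else {
    NULL
  }
  list(computable = !is.null(tau), tau_report = tau, kw_report = kw)
}
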