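#' Global climate PCA for niche-volume estimation
#'
#' Standardised PCA over the environment of every valid raster cell - the
#' full set of available climates - giving one shared low-dimensional space
#' in which every species' native niche volume is estimated, so volumes are
#' comparable across species. Zero-variance layers are dropped with a
#' warning.
#'
#' @param stack A [climate_stack()].
#' @param n_dims Number of retained axes (default 3; kernel density
#'   estimation in many more dimensions is vacuous at realistic sample
#'   sizes).
#' @return Object of class `global_climate_pca` with the standardisation,
#'   loadings (`k x n_dims`), and explained variance per axis.
#' @export
fit_global_pca <- function(stack, n_dims = 3L) {
  env <- stack_cell_env(stack)
  mu <- colMeans(env)
  sdv <- apply(env, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping zero-variance layer(s): ",
            paste(colnames(env)[!keep], collapse = ", "))
  }
  vars <- colnames(env)[keep]
  stopifnot(sum(keep) >= n_dims)
  x <- sweep(sweep(env[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  pca <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  structure(
    list(mean = mu[keep], sd = sdv[keep], vars = vars,
         loadings = pca$rotation[, seq_len(n_dims), drop = FALSE],
         explained_var = pca$sdev^2 / sum(pca$sdev^2),
         n_dims = as.integer(n_dims)),
    class = "global_climate_pca"
  )
}

#' Project environmental values into the global climate PCA space
#'
#' @param env Environmental matrix including the PCA variables.
#' @param pca A `global_climate_pca` from [fit_global_pca()].
#' @return `n x n_dims` score matrix.
#' @export
project_global <- function(env, pca) {
  stopifnot(inherits(pca, "global_climate_pca"))
  x <- env[, pca$vars, drop = FALSE]
  x <- sweep(sweep(x, 2, pca$mean), 2, pca$sd, "/")
  x %*% pca$loadings
}

#' Per-axis Silverman bandwidths
#'
#' The conventional free-bandwidth estimator for Gaussian kernels:
#' `b_j = 1.06 * SD_j * n^(-1/5)` for each axis j.
#'
#' @param scores `n x d` score matrix (n >= 2).
#' @return Numeric vector of d bandwidths.
#' @export
silverman_bandwidth <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(n >= 2L)
  b <- 1.06 * apply(scores, 2, stats::sd) * n^(-1 / 5)
  if (any(b <= 0)) {
    warning("zero spread on some axis; bandwidth set to machine-epsilon scale")
    b[b <= 0] <- sqrt(.Machine$double.eps)
  }
  b
}

#' Fixed bandwidth shared by all species
#'
#' Hypervolumes are computed preliminarily with free per-axis bandwidths;
#' the single bandwidth then fixed for every species (and axis) is the
#' maximum over species of the maximum per-axis Silverman bandwidth, so no
#' species' kernel is narrower than its own free choice would have been.
#'
#' @param all_species_scores List of `n x d` score matrices, one per
#'   species.
#' @param per_species When `TRUE`, return each species' own max per-axis
#'   bandwidth instead of the shared global maximum.
#' @return Scalar bandwidth, or a numeric vector when `per_species`.
#' @export
fixed_bandwidth <- function(all_species_scores, per_species = FALSE) {
  stopifnot(length(all_species_scores) >= 1L)
  b <- vapply(all_species_scores,
              function(s) max(silverman_bandwidth(s)), numeric(1))
  if (per_species) b else max(b)
}

# Internal: Gaussian-mixture KDE (isotropic SD b, equal weights at the data
# points) evaluated at query points, in evaluation batches.
.gaussian_mixture_density <- function(query, centers, b, chunk = 500L) {
  d <- ncol(centers)
  n <- nrow(centers)
  norm_const <- (2 * pi * b^2)^(d / 2) * n
  out <- numeric(nrow(query))
  c2 <- rowSums(centers^2)
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), c2, "+") - 2 * q %*% t(centers)
    d2[d2 < 0] <- 0
    out[idx] <- rowSums(exp(-d2 / (2 * b^2))) / norm_const
  }
  out
}

#' Gaussian kernel density hypervolume
#'
#' Estimates the volume of the climatic niche as the volume of the
#' superlevel set of a Gaussian kernel density estimate holding a fraction
#' `q` of the probability mass. The KDE `f` is an equal-weight mixture of
#' isotropic Gaussians (SD `b`) at the data points. `n_samples` points are
#' drawn from `f`; the density threshold `f*` is the value such that samples
#' with `f >= f*` carry fraction `q` of the estimated mass, and the volume
#' of `{f >= f*}` is the importance-sampling estimate
#' `mean(ifelse(f(x_i) >= f*, 1 / f(x_i), 0))`.
#'
#' @param scores `n x d` matrix of points in climate PCA space (n >= 2).
#' @param b Scalar kernel bandwidth (e.g. from [fixed_bandwidth()]).
#' @param q Probability mass quantile of the level set, in (0, 1); default
#'   0.95.
#' @param n_samples Monte Carlo sample count (default `10000 * d`,
#'   minimum 1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param species_id Optional label carried into the result.
#' @return Object of class `hypervolume_result` with fields `species_id`,
#'   `n_dims`, `bandwidth`, `quantile`, `volume` (PCA-space units^d),
#'   `n_samples`, `seed`.
#' @export
gaussian_hypervolume <- function(scores, b, q = 0.95, n_samples = NULL,
                                 seed = 1L, species_id = NA_character_) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  d <- ncol(scores)
  stopifnot(n >= 2L, d >= 1L, b > 0)
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  if (is.null(n_samples)) n_samples <- 10000L * d
  if (n_samples < 1000L) stop("n_samples must be at least 1000")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  idx <- sample.int(n, n_samples, replace = TRUE)
  noise <- matrix(stats::rnorm(n_samples * d), n_samples, d) * b
  draws <- scores[idx, , drop = FALSE] + noise
  f <- .gaussian_mixture_density(draws, scores, b)

  # samples are f-distributed, so the mass of {f >= f*} is estimated by the
  # fraction of samples above f*; keep the q highest-density samples
  ord <- order(f, decreasing = TRUE)
  n_keep <- max(1L, ceiling(q * n_samples))
  kept <- ord[seq_len(n_keep)]
  volume <- sum(1 / f[kept]) / n_samples

  structure(
    list(species_id = species_id, n_dims = d, bandwidth = b, quantile = q,
         volume = volume, n_samples = as.integer(n_samples),
         seed = as.integer(seed)),
    class = "hypervolume_result"
  )
}

#' @export
print.hypervolume_result <- function(x, ...) {
  cat(sprintf(
    "hypervolume: %s | %d dims, b = %.4g, q = %.2f -> volume %.4g\n",
    x$species_id, x$n_dims, x$bandwidth, x$quantile, x$volume))
  invisible(x)
}
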