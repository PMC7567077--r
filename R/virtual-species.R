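#' Ground-truth parameters of a simulated virtual species
#'
#' Describes the Gaussian suitability surface in standardised environment
#' space from which occurrences are drawn, the niche-centroid displacement
#' applied to the non-native population, and the fraction of non-native
#' occurrences placed in climates outside the native population's occupied
#' environmental envelope.
#'
#' With scalar parameters (the default and recommended mode) the niche is
#' defined on the landscape's dominant climatic gradient: the leading PCA
#' axis of the standardised cell environments, rescaled to unit SD over the
#' map and oriented from the native towards the non-native window's
#' climates. Suitability is then a 1-D Gaussian in that coordinate, the
#' remaining climatic variation entering only through availability - the
#' way species respond in practice to one or two dominant climate axes, and
#' robust across landscape realisations. `niche_center`, `niche_breadth`
#' and `shift_delta` are all in units of the gradient's map-wide SD.
#' Vector-valued parameters switch to a full-dimensional Gaussian kernel
#' `exp(-0.5 * sum(((x - center) / breadth)^2))` on the standardised
#' per-layer environment `x`.
#'
#' @param niche_center Niche optimum (gradient units, scalar), or `NULL`
#'   (default) for the mean gradient score of the native window - a
#'   species adapted to its home region. A vector is a full-dimensional
#'   optimum in standardised per-layer units.
#' @param niche_breadth Positive; suitability SD (gradient units, or
#'   per-layer when vector). Default 1.
#' @param shift_delta Niche-centroid displacement applied to the
#'   non-native population, in gradient-SD units (scalar); a vector is a
#'   full-dimensional displacement. Default 0.
#' @param target_expansion Fraction in `[0, 1]` of non-native occurrences
#'   placed in climates outside the native envelope. Default 0.
#' @param seed Integer seed for occurrence sampling.
#' @return An object of class `virtual_species_truth`.
#' @export
virtual_species_truth <- function(niche_center = NULL, niche_breadth = 1,
                                  shift_delta = 0, target_expansion = 0,
                                  seed = 1L) {
  stopifnot(all(niche_breadth > 0),
            target_expansion >= 0, target_expansion <= 1)
  structure(
    list(niche_center = niche_center, niche_breadth = niche_breadth,
         shift_delta = shift_delta, target_expansion = target_expansion,
         seed = as.integer(seed)),
    class = "virtual_species_truth"
  )
}

# Internal: do two geographic rectangles (xmin,xmax,ymin,ymax) overlap?
.windows_overlap <- function(a, b) {
  a$xmin < b$xmax && b$xmin < a$xmax && a$ymin < b$ymax && b$ymin < a$ymax
}

#' Simulate native and non-native occurrences of a virtual species
#'
#' Native occurrences are drawn from the cells of `native_window` with
#' probability proportional to a Gaussian suitability
#' `exp(-0.5 * sum(((x - center) / breadth)^2))` of each cell's
#' standardised environment `x`; non-native occurrences are drawn from
#' `nonnative_window` under the same kernel with the centre displaced by
#' `shift_delta`. Point coordinates are jittered uniformly within their
#' cell.
#'
#' The expansion dial controls how much of the non-native population sits
#' in novel climates. A fraction `target_expansion` of the non-native rows
#' is placed in cells whose raw environment lies outside the native
#' occurrences' per-layer min/max envelope *and* whose position along the
#' dominant climatic gradient lies beyond the native envelope by a safety
#' margin (relaxed stepwise when the window holds too few such cells), so
#' the injected novelty is separable rather than scattered across
#' dimensions. The remaining rows are drawn from cells inside the
#' envelope. Because downstream cleaning collapses records to one per
#' cell, the number of distinct novel cells is matched to the familiar
#' cells' occupancy rate, which makes the availability-corrected occupancy
#' share of novel climates track `target_expansion`.
#'
#' @param stack A [climate_stack()].
#' @param truth A [virtual_species_truth()].
#' @param native_window,nonnative_window Disjoint geographic rectangles,
#'   lists with `xmin`, `xmax`, `ymin`, `ymax` (degrees).
#' @param n_native,n_nonnative Occurrence counts (each >= 10, matching the
#'   pipeline's minimum usable sample).
#' @param species Species label for the output table.
#' @return Occurrence data.frame with columns `species`, `status`
#'   (`native`/`nonnative`), `lon`, `lat`. Deterministic given
#'   `truth$seed`.
#' @export
generate_virtual_species <- function(stack, truth, native_window,
                                     nonnative_window,
                                     n_native = 200L, n_nonnative = 100L,
                                     species = "sp1") {
  stopifnot(inherits(stack, "climate_stack"),
            inherits(truth, "virtual_species_truth"),
            n_native >= 10L, n_nonnative >= 10L)
  if (.windows_overlap(native_window, nonnative_window)) {
    stop("native and non-native windows must be disjoint")
  }

  env <- stack_cell_env(stack)
  mu <- colMeans(env)
  sdv <- apply(env, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(env, 2, mu), 2, sdv, "/")
  k <- ncol(env)
  lon <- attr(env, "lon")
  lat <- attr(env, "lat")
  in_window <- function(w) {
    which(lon >= w$xmin & lon <= w$xmax & lat >= w$ymin & lat <= w$ymax)
  }
  nat_cells_all <- in_window(native_window)
  non_cells_all <- in_window(nonnative_window)
  if (length(nat_cells_all) == 0L) stop("native window contains no valid climate cells")
  if (length(non_cells_all) == 0L) stop("non-native window contains no valid climate cells")

  # dominant climatic gradient: leading PCA axis of the standardised cells,
  # rescaled to unit SD over the map and oriented so the non-native
  # window's climates score higher than the native window's
  rot <- stats::prcomp(z, center = FALSE, scale. = FALSE)$rotation
  s_all <- as.numeric(z %*% rot[, 1])
  s_all <- s_all / stats::sd(s_all)
  gap <- mean(s_all[non_cells_all]) - mean(s_all[nat_cells_all])
  if (gap < 0) s_all <- -s_all

  gradient_mode <- length(truth$niche_center %||% 0) == 1L &&
    length(truth$niche_breadth) == 1L && length(truth$shift_delta) == 1L
  if (gradient_mode) {
    center <- if (is.null(truth$niche_center)) {
      mean(s_all[nat_cells_all])
    } else {
      as.numeric(truth$niche_center)
    }
    breadth <- as.numeric(truth$niche_breadth)
    center2 <- center + as.numeric(truth$shift_delta)
    log_suit <- function(cells, ctr) {
      -0.5 * ((s_all[cells] - ctr) / breadth)^2
    }
  } else {
    center <- if (is.null(truth$niche_center)) {
      colMeans(z[nat_cells_all, , drop = FALSE])
    } else {
      rep_len(truth$niche_center, k)
    }
    breadth_v <- rep_len(truth$niche_breadth, k)
    delta <- truth$shift_delta
    delta_vec <- if (length(delta) == 1L) {
      as.numeric(delta) * rot[, 1] * sign(gap)
    } else {
      rep_len(delta, k)
    }
    center2 <- center + delta_vec
    log_suit <- function(cells, ctr) {
      zz <- sweep(z[cells, , drop = FALSE], 2, ctr)
      -0.5 * rowSums(sweep(zz, 2, breadth_v, "/")^2)
    }
  }

  draw_cells <- function(cells, ctr, n, replace = TRUE) {
    lw <- log_suit(cells, ctr)
    w <- exp(lw - max(lw))
    cells[sample.int(length(cells), n, replace = replace, prob = w)]
  }
  jitter_points <- function(cells) {
    cs <- stack$cellsize
    data.frame(
      lon = lon[cells] + stats::runif(length(cells), -cs / 2, cs / 2),
      lat = lat[cells] + stats::runif(length(cells), -cs / 2, cs / 2)
    )
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$seed)

  nat_cells <- draw_cells(nat_cells_all, center, n_native)
  nat_pts <- jitter_points(nat_cells)

  # occupied environmental envelope of the native population (raw units)
  nat_env <- env[nat_cells, , drop = FALSE]
  env_lo <- apply(nat_env, 2, min)
  env_hi <- apply(nat_env, 2, max)
  outside_box <- rowSums(
    sweep(env[non_cells_all, , drop = FALSE], 2, env_lo, "<") |
      sweep(env[non_cells_all, , drop = FALSE], 2, env_hi, ">")) > 0

  # native population's footprint on the gradient, for the novelty margin
  s_grad_nat <- s_all[nat_cells]
  s_grad_non <- s_all[non_cells_all]
  rng <- range(s_grad_nat)
  sdn <- stats::sd(s_grad_nat)

  n_exp <- round(truth$target_expansion * n_nonnative)
  n_fam <- n_nonnative - n_exp
  non_cells <- integer(0)

  if (n_fam > 0L) {
    non_cells <- draw_cells(non_cells_all, center2, n_fam)
  }

  if (n_exp > 0L) {
    pool_nov <- non_cells_all[outside_box]
    for (m in c(4, 3, 2, 1, 0)) {
      sel <- outside_box &
        (s_grad_non > rng[2] + m * sdn | s_grad_non < rng[1] - m * sdn)
      if (sum(sel) >= 15L) {
        pool_nov <- non_cells_all[sel]
        break
      }
    }
    if (length(pool_nov) == 0L) {
      warning("non-native window holds no climates outside the native ",
              "envelope; expansion fraction not enforced")
      non_cells <- c(non_cells, draw_cells(non_cells_all, center2, n_exp))
    } else {
      # downstream cleaning keeps one record per cell, and with roughly
      # uniform climate availability along the niche axis the corrected
      # occupancy share of novel climates equals the share of distinct
      # occupied cells; so the number of distinct novel cells is set to
      # te / (1 - te) times the familiar cell count
      k_fam <- length(unique(non_cells))
      te <- truth$target_expansion
      k_nov <- if (te >= 1) {
        min(n_exp, length(pool_nov))
      } else {
        max(2L, min(n_exp, length(pool_nov),
                    round(te / (1 - te) * k_fam)))
      }
      # novel cells are drawn uniformly over the pool rather than by
      # suitability: an expanding population released from its climatic
      # constraint spreads across the novel climates instead of hugging
      # the envelope boundary
      cells_nov <- if (k_nov >= length(pool_nov)) {
        pool_nov
      } else {
        pool_nov[sample.int(length(pool_nov), k_nov, replace = FALSE)]
      }
      non_cells <- c(rep(cells_nov, length.out = n_exp), non_cells)
    }
  }
  non_pts <- jitter_points(non_cells)

  out <- data.frame(
    species = species,
    status = rep(c("native", "nonnative"), c(n_native, n_nonnative)),
    lon = c(nat_pts$lon, non_pts$lon),
    lat = c(nat_pts$lat, non_pts$lat),
    stringsAsFactors = FALSE
  )
  .check_occ(out)
  out
}
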