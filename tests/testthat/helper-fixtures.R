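# Shared small synthetic world, built once per test run.

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      stack <- generate_climate_stack(
        n_layers = 6,
        grid = list(nrow = 30L, ncol = 30L, xmin = 0, ymax = 30, cellsize = 1),
        correlation = 0.3, trend = 3, seed = 42
      )
      cache <<- list(
        stack = stack,
        nat_w = list(xmin = 1, xmax = 13, ymin = 2, ymax = 28),
        non_w = list(xmin = 16, xmax = 29, ymin = 2, ymax = 28),
        polygons = generate_polygon_map(
          5, 5, list(xmin = 0, xmax = 30, ymin = 0, ymax = 30))
      )
    }
    cache
  }
})

# occurrences + per-range env/background for one virtual species
small_species <- function(truth, n_native = 80L, n_nonnative = 50L) {
  w <- small_world()
  occ <- generate_virtual_species(w$stack, truth, w$nat_w, w$non_w,
                                  n_native, n_nonnative)
  clean <- suppressMessages(preprocess_occurrences(occ, w$stack))$occ
  nat <- clean[clean$status == "native", , drop = FALSE]
  non <- clean[clean$status == "nonnative", , drop = FALSE]
  list(
    occ = clean,
    env_nat = extract_env(nat, w$stack),
    env_non = extract_env(non, w$stack),
    bg_nat = range_background(nat, w$stack),
    bg_non = range_background(non, w$stack)
  )
}

# two Gaussian clouds in env space (no raster), for axis/metric tests
gaussian_clouds <- function(n1 = 60, n2 = 60, d = 5, sep = 0, seed = 1,
                            rho = 0.3) {
  set.seed(seed)
  sig <- matrix(rho, d, d)
  diag(sig) <- 1
  cl <- chol(sig)
  mk <- function(n, mu) {
    m <- matrix(stats::rnorm(n * d), n) %*% cl
    m <- sweep(m, 2, rep(mu, d), "+")
    colnames(m) <- paste0("v", seq_len(d))
    m
  }
  list(a = mk(n1, 0), b = mk(n2, sep))
}
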