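Package: nicheshift
Title: Quantifying Climatic Niche Shifts Between Native and Non-Native Ranges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying realized climatic niche
    shifts of alien species between their native and non-native ranges.
    Occurrence records are cleaned (nearest-neighbour thinning, per-cell
    deduplication, minimum-sample filtering), reduced to a single
    discriminant climatic axis by principal component analysis followed by
    between-class analysis, and converted into kernel-smoothed,
    availability-corrected occupancy densities on a binned niche axis.
    Niche change is measured by Schoener's D overlap, percent niche
    expansion into novel climates, and a permutation niche-equivalency
    test with Benjamini-Hochberg correction. Geographic dispersion is
    summarised by polygon richness and Rao quadratic entropy on polygon
    centroids, with k-means classification into dispersion groups, and
    native niche volume is estimated by Gaussian kernel density
    hypervolumes in a global climate PCA space. A seeded virtual-species
    simulator generates self-contained synthetic climate rasters,
    occurrences with known true niche shift, and polygon maps for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
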