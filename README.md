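# nicheshift

Quantifying realized climatic niche shifts of alien species between their
native and non-native ranges.

When a species establishes outside its native range it may stay within the
climates it occupied at home or colonise novel ones. `nicheshift`
implements an end-to-end, reproducible pipeline for measuring this across
many species — the workflow used in comparative invasion biogeography — and
ships a seeded virtual-species simulator with known ground truth so every
stage can be validated without external data downloads.

## The metrics

Occurrences of one species (cleaned by nearest-neighbour thinning, per-cell
deduplication and a minimum-10-records-per-range filter) are reduced to a
single discriminant climatic axis: PCA of the standardised bioclimatic
variables followed by a between-class analysis on the leading 10 components
with the two ranges as classes. On 100 bins along this axis, kernel-smoothed
occurrence densities are corrected for climate availability, giving the
occupancy `z ∝ o / e`. Niche change between the native and non-native
occupancies `z1, z2` is then measured by

- **Schoener's D** `= 1 − ½ Σ |z1 − z2|` (0 = disjoint, 1 = identical);
- **Expansion** = % of non-native occupancy in climates where the native
  niche is absent, classed `low`/`high` at 10%;
- a **niche-equivalency permutation test**: occurrences pooled and re-split
  1000 times at the observed ratio, one-sided p for low D, with
  Benjamini–Hochberg correction across species.

Geographic dispersion is summarised by the number of occupied polygons and
**Rao quadratic entropy** `Q = Σ p_i p_j d_ij` over occupied polygon
centroids (haversine km), with k-means classification into regional /
transcontinental / global groups; native niche size is a **Gaussian kernel
hypervolume** in a 3-axis PCA of all available climates, with a two-pass
fixed bandwidth shared by all species. A statistics layer (Kruskal–Wallis,
Pearson chi-squared, Dunn post-hoc with BH, Kendall tau-b) relates the
metrics to invasiveness labels and dispersion groups.

## A worked example

Simulate a small cohort of virtual ant-like species with known true niche
shifts and run the whole pipeline:

```r
library(nicheshift)

sim <- simulate_cohort(n_species = 8, seed = 42)
cfg <- run_config(n_reps = 199, seed = 42)
res <- run_all(sim$stack, sim$occurrences, sim$polygons, sim$labels,
               config = cfg)
merge(res$species_table, sim$truth, by.x = "species_id", by.y = "species")
```

```
  species_id shift_delta target_expansion     D expansion_pct p_equiv_adj richness            group
1      sp001           0             0.00 0.843         13.40       0.005       37           global
2      sp002           1             0.00 0.618          8.75       0.005       30 transcontinental
3      sp003           2             0.00 0.685         25.77       0.005       16         regional
4      sp004           3             0.00 0.196         78.72       0.005       33 transcontinental
5      sp005           0             0.25 0.614         36.28       0.005       37           global
6      sp006           1             0.25 0.613         31.07       0.005       27 transcontinental
7      sp007           2             0.25 0.415         58.54       0.005       34           global
8      sp008           3             0.25 0.135         86.22       0.005       41           global
```

Reading the table: `D` falls as the dialled niche displacement
(`shift_delta`, in climate-gradient SDs) grows — compare sp001 (no shift,
D = 0.84) with sp004 and sp008 (3 SD, D ≈ 0.14–0.20) — and `expansion_pct`
rises with the injected fraction of novel-climate occurrences. Every
species rejects niche equivalency here (adjusted p = 0.005, the smallest
value 199 permutations allow) because the simulated non-native region is
climatically offset, so even unshifted species occupy distinguishable
climates — the availability-driven signal the equivalency test is designed
to detect. `richness` and the dispersion `group` come from the polygon
map; `res$tests` holds the cohort-level comparisons and `res$cleaning_report`
accounts for every dropped record.

The methods vignette (`vignettes/niche-shift-methods.Rmd`) documents the
model, every tunable parameter, the simulator's ground-truth dials, and the
numerical conventions.

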