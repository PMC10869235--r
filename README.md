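# mitomorph

Quantitative 3D morphometry of mitochondria and their cristae from volume
electron microscopy (SBF-SEM) instance segmentations, for tissue biologists
comparing organelle ultrastructure between experimental groups — the
motivating case is adult versus aged murine brown adipose tissue (BAT),
where aging enlarges and complexifies mitochondria while depleting their
cristae.

The package consumes co-registered 3D integer *label volumes* (one for
mitochondria, one for cristae; multi-page TIFF or NRRD, anisotropic voxels,
nominally 10 × 10 × 50 nm) and a blinded cristae-score annotation table, and
produces per-object metric tables, two-group statistics, and volume-binned
"otyping" galleries. Because such volumes are rarely public, it also ships a
first-class synthetic phantom generator with analytic ground truth, so the
entire pipeline is testable end to end.

## The metrics at its core

For each reconstructed object of volume *V* and surface area *SA*:

- **sphericity**  ψ = π^⅓ (6V)^⅔ / SA — 1 for a perfect sphere, lower for
  elongated or branched shapes;
- **mitochondrial complexity index**  MCI = SA³ / (16π²V²) — scale-invariant,
  9/4π ≈ 0.716 for a sphere, rising with branching and surface elaboration;
- the two are algebraically locked: MCI · ψ³ = 9/4π, which the pipeline
  asserts to 1e-12 on every emitted row;
- **perimeter** — mean per-z-slice contour length of the 2D cross-section
  (an operational definition; `sum`/`max` reducers available);
- per crista: volume, area, perimeter **normalized by the parent
  mitochondrion's volume**; per mitochondrion: **cristae density**
  (Σ cristae volume / mito volume) and **matrix volume** (the complement);
- cristae **scores** (ordinal 1–4, blinded human ratings) are ingested,
  consensus-merged (median, ties toward the worse call) and aggregated into
  frequency/percentage histograms and mean ± SEM comparisons.

Volume is voxel-exact; surface area comes from marching-tetrahedra meshing
of a Gaussian-smoothed occupancy field (≈4% on digitized spheres, versus
+36% meshing the raw mask and +50% counting voxel faces); group comparisons
use Welch's t with an automatic switch to Mann-Whitney when a normality
screen fails, both p-values always recorded, stars at p < 0.05/0.01/0.001/0.0001.

## Worked example

Simulate a small two-group cohort (2 animals × 20 mitochondria per group),
measure everything, and compare the groups:

```r
library(mitomorph)

spec <- cohort_spec(n_animals = 2, n_objects = 20, seed = 7)
res  <- simulate_and_measure(spec)

head(res$mito, 4)
#> # A tibble: 4 x 7
#>   source_id object_id volume_um3 surface_area_um2 perimeter_um sphericity   mci
#>   <chr>         <int>      <dbl>            <dbl>        <dbl>      <dbl> <dbl>
#> 1 adult_m1          1      0.302             3.29         1.72      0.662 2.47
#> 2 adult_m1          2      1.11              5.39         3.27      0.964 0.799
#> 3 adult_m1          3      0.876             4.59         3.03      0.965 0.798
#> 4 adult_m1          4      0.299             2.24         2.02      0.964 0.801

cmp <- compare_cohort(res, res$scores, res$groups)
cmp |>
  dplyr::filter(level == "object") |>
  dplyr::select(metric, test, p_value, mean_a, mean_b, direction, stars) |>
  as.data.frame()
#>              metric         test  p_value mean_a mean_b direction stars
#> 1        volume_um3 mann_whitney 7.77e-01 0.3316 0.4227  increase    ns
#> 2  surface_area_um2 mann_whitney 7.18e-01 2.5291 2.9838  increase    ns
#> 3      perimeter_um      welch_t 3.83e-01 2.0503 2.1581  increase    ns
#> 4        sphericity mann_whitney 1.70e-01 0.8943 0.8751  decrease    ns
#> 5               mci mann_whitney 1.70e-01 1.1369 1.2396  increase    ns
#> 6       norm_volume mann_whitney 5.85e-58 0.0315 0.0134  decrease  ****
#> 7         norm_area mann_whitney 4.01e-49 1.7540 0.7880  decrease  ****
#> 8    norm_perimeter mann_whitney 1.40e-70 3.2050 1.5040  decrease  ****
#> 9   cristae_density      welch_t 1.88e-15 0.3002 0.1753  decrease  ****
#> 10            score mann_whitney 4.23e-11 3.3250 1.7000  decrease  ****
```

Row 1 of `res$mito` is a branched object (sphericity 0.66, MCI 2.5); rows
2–4 are near-spheres (ψ ≈ 0.96, MCI ≈ 0.8, the spherical floor being
9/4π ≈ 0.716). In the comparison table the cristae effects (normalized
volume/area/perimeter, density, score — all decreased in "aged") are
already unmistakable at 40 objects per group, while the mitochondrial size
and shape effects go the planted way (`direction`) but need the full study
scale (3 × 100 per group, `cohort_spec()` defaults) to reach significance.

For measured data instead of phantoms: `read_label_volume()` the TIFF/NRRD
pair, `measure_all()` each volume, `assign_cristae()` +
`cristae_records()` + `summarize_cristae_by_mito()` to nest cristae,
`ingest_scores()` for the annotation CSV, then the same `compare_*`,
`make_otype_panel()`/`render_gallery()` and `plot_comparison()` calls. A
file-based orchestration of all stages, with a serialized re-runnable
config, is `run_pipeline()` (thin CLI wrapper in `inst/cli/mitomorph.R`).

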