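# selscape

Habitat-selection analysis with random forests on synthetic landscapes.

`selscape` is a reusable resource-selection-function (RSF) pipeline for
spatial ecologists: from a categorical habitat raster and animal telemetry to
a tuned use-availability random forest and its full interpretation. Because
it ships a synthetic-data module with a *known true selection function*,
every stage of the analysis can be validated by recovering a planted truth —
no data download is needed.

The pipeline mirrors a two-scale carnivore telemetry study on a five-class
landscape (forest, agriculture, grassland, open water, developed):

1. **Landscape simulation** — calibrated five-class mosaics (e.g. 54%
   forest / 35% agriculture) plus major/minor road polylines.
2. **Covariates** — seven Euclidean distance grids (signed for forest: the
   distance axis runs negative into the forest interior) and a moving-window
   Shannon evenness grid, `HE = -Σ P_i ln P_i / ln 5` in [0, 1].
3. **Telemetry simulation** — individuals with uniform-disc availability,
   used points rejection-sampled from a true RSF `w(z)`, isotropic location
   error parameterized by mean displacement (default 94 m).
4. **Ranges** — study area by buffer–dissolve (exact circular-arc union
   geometry) and 95% kernel home ranges with a two-stage direct plug-in
   bandwidth.
5. **Design** — per-individual use-availability tables at both selection
   scales, with the available-point ratio stabilization diagnostic over
   ratios 1:1, 1:2, 1:5, 1:10, 1:20.
6. **Model** — a subsampling CART/Gini random forest (propensity = vote
   fraction), tuned by out-of-bag error over trees x mtry x fraction, with
   OOB permutation importance.
7. **Interpretation** — partial-dependence curves, the 10x10-binned two-way
   interaction RMSE ranking with max-drop cutoff, and a projected selection
   raster (sex averaged out).
8. **Validation** — leave-one-individual-out cross-validation scored by ROC
   AUC (mean ± SE across individuals).

All artifacts are plain text (ESRI ASCII grids, GeoJSON, CSV, JSON/YAML) and
every stage is reproducible from a single base seed.

## Worked example

```r
library(selscape)

cfg <- landscape_config(n_rows = 120, n_cols = 120, cell_size = 30,
                        smoothing_length = 200, seed = 42)
map <- generate_landscape(cfg)
map
#> habitat_map: 120 x 120 cells, 30 m resolution
#>      forest agriculture   grassland       water   developed
#>      0.5399      0.3494      0.0391      0.0225      0.0491

roads <- generate_roads(cfg)
stack <- build_covariates(map, roads, window_radius = 300)

# six animals that prefer forest interiors far from agriculture
inds <- simulate_individuals(6, c(3, 3), map, mean_hr_area = pi * 450^2,
                             seed = 42, n_points_mean = 80, n_points_sd = 8)
rsf  <- rsf_log_linear(coefs = c(dist_agriculture = 0.012,
                                 dist_forest_signed = -0.010))
tel  <- simulate_telemetry(inds, stack, rsf, seed = 43)
tel  <- apply_location_error(tel, 94, map$geom, seed = 44)

sa  <- clip_region(study_area(tel, 450), as_region(map))
tab <- build_table(tel, stack, sa, ratio = 10, scale = "study_area", seed = 45)

fit <- fit_forest(tab, forest_config(n_trees = 200, mtry = 3, seed = 46))
fit
#> fitted_forest: 200 trees, mtry 3 , fraction 0.623 | OOB error 0.0752

head(permutation_importance(fit, tab, seed = 47), 4)
#>            predictor importance           se rank
#> 1 dist_forest_signed 0.03253425 0.0011729641    1
#> 2         dist_water 0.02743151 0.0009311692    2
#> 3    dist_major_road 0.02122554 0.0008993752    3
#> 4     dist_developed 0.01926614 0.0006853051    4

partial_dependence(fit, tab, "dist_agriculture", n_grid = 5)
#>       grid dependence
#> 1   0.0000 0.07625899
#> 2 127.2792 0.08222801
#> 3 300.0000 0.09844136
#> 4 647.3049 0.17231652

loio_cv(tab, forest_config(n_trees = 100, mtry = 3, seed = 48))
#> cv_result: mean AUC 0.633 +/- 0.102 (SE) over 6 individuals
```

Reading the output: the planted RSF prefers forest interiors
(`dist_forest_signed` coefficient < 0) and avoids agriculture, and the
forest recovers it — the signed forest distance ranks first in permutation
importance, the partial dependence on `dist_agriculture` rises with distance
from agriculture (propensity 0.076 at the edge vs 0.172 at ~650 m), and the
OOB error (0.075) beats the 1:10 no-information rate (0.091). The
leave-one-individual-out AUC (0.63 ± 0.10) is modest at this desk scale —
six animals on a 3.6 km map — and rises above 0.75 in the package's
acceptance scenarios with 27 individuals.

## Full pipeline

A YAML-configured end-to-end run (all stages, both scales, manifest with
md5 checksums):

```r
cfg <- pipeline_config(system.file("extdata", "smoke_config.yaml",
                                   package = "selscape"))
run_pipeline(cfg)
```

or from the shell, stage by stage:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "selscape", package = "selscape"))') \
    run-all --config my_config.yaml
```

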