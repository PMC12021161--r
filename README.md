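# herdscan

Nomadic pastoralist settlements are routinely missed by censuses and
health campaigns: they are small, remote, and move. Manual enumeration
from satellite imagery works but cannot scale to the thousands of square
kilometers a national campaign must cover. herdscan is an R package for
the computational side of that problem: it classifies 128 m satellite
image tiles as containing an active settlement or not, fuses public road
and waterway proximity data into the classifier through a Gaussian
discriminant analysis (GDA), calibrates a decision threshold for high
recall, scans whole regions, and merges positive tiles into a short,
ranked worklist for manual review. It is aimed at researchers in
geospatial epidemiology and demographic surveillance who need a
reproducible, inspectable pipeline rather than a GPU cluster.

Because settlement imagery is rarely shareable, the package includes a
first-class synthetic scene simulator (seeded, byte-reproducible,
georeferenced) that emulates the statistical structure the method relies
on — dark circular livestock enclosures for occupied settlements, broken
burn-scarred remnants for abandoned ones, stratified negatives, and
class-conditional infrastructure distances. Every stage of the pipeline
is tested end to end on it.

## The model

A tile `x` is scored by a CNN encoder and dense head,
`P(y=1|x) = f(E(x))`, trained with unweighted binary cross-entropy
(Adam, batch 16, learning rate 0.001, up to 40 epochs, best validation
epoch kept). Infrastructure proximity enters through a per-kind GDA on
the distance `D` from the tile center to the nearest road or waterway:

    y ~ Bernoulli(xi),   D | y=0 ~ N(mu0, sigma0^2),   D | y=1 ~ N(mu1, sigma1^2)

with all parameters fit by maximum likelihood — efficient enough to be
estimated from a few dozen labeled points, which is exactly the low-data
regime where image-only training struggles. Bayes' rule converts a
distance into `P(y=1|d)`, and the class densities plus posterior are
fused into the classifier at the embedding (`aux2`), logit (`aux1`), or
both (`aux12`) insertion points. Evaluation centers on **precision at
0.95 recall** — the precision achievable while keeping 95% of known
settlements — alongside AUPRC and top F1, all computed by exact
threshold enumeration with tie grouping.

## Worked example

Simulate a 24 x 24 km scene with 60 active settlements, fit a waterway
GDA on a held-out subset, train the default small CNN, calibrate a
0.95-recall threshold, and scan a 4 x 4 km corner of the region:

```r
library(herdscan)

cfg    <- demo_scene_config(n_active = 60, seed = 1)
bundle <- generate_scene(cfg)
bundle
#> <scene_bundle> 24000 x 24000 m @ 0.5 m/px; 4 roads, 4 waters; 180 points (60 active)

manifest <- make_labeled_dataset(bundle, seed = 1)
rec  <- compute_distance_features(manifest, bundle$roads, bundle$waters)
hold <- gda_holdout_split(manifest$label, 0.2, seed = 1)
gda  <- fit_gda(rec$d_water_m[hold$fit], manifest$label[hold$fit], "water")
gda
#> <gda_model:water> xi=0.333  active: N(200.9, 65.0^2) n=12  other: N(1757.3, 767.0^2) n=24
round(posterior_probability(gda, c(100, 500, 2000)), 3)
#> [1] 0.948 0.001 0.000

tr <- manifest[manifest$split == "train", ]
va <- manifest[manifest$split == "validation", ]
fit <- train(build_model("small_cnn", seed = 1),
             load_tiles(bundle, tr), tr$label,
             load_tiles(bundle, va), va$label,
             training_config(max_epochs = 8, seed = 1))
tail(fit$history, 3)
#>   epoch train_loss val_auprc val_precision_at_recall
#> 1     6      0.534     0.980                   0.818
#> 2     7      0.493     1                       1
#> 3     8      0.435     1                       1

alpha <- calibrate_threshold(predict_proba(fit$model, load_tiles(bundle, va)),
                             va$label)                     # 0.391
grid <- build_tile_grid(c(4096, 4096), 128, 0.5)
scan <- scan_region(fit$model, bundle, grid, alpha)
det  <- merge_detections(scan, grid)
reduction_report(attr(det, "total_tiles_scanned"), det)
#> <reduction_report> 1,024 tiles -> 14 for review (73.1-fold reduction)
```

Read: a settlement 100 m from a waterway has posterior 0.95 of being
active on distance alone; the trained classifier separates the
validation tiles by epoch 7; and scanning 1,024 tiles at the calibrated
threshold leaves 14 merged candidates to review — a 73-fold reduction of
the manual workload on this small window.

A command-line wrapper over the same functions (simulate / features /
fit-gda / train / evaluate / scan) is installed at
`inst/cli/herdscan.R`; real inputs are TIFF rasters with world-file
georeferencing, GeoJSON infrastructure, and CSV manifests in a projected
CRS.

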