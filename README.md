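# mpmimage

Automated image analysis of 3D cancer–endothelial co-culture
microphysiological models: **cell coverage area**, **cancer invasion
depth**, and **microvessel network structure** from multi-channel
fluorescence Z-stacks acquired on non-confocal plate readers.

Manual quantification of these readouts — thresholding projections in image
editors, scrolling through Z-stacks to find the deepest invaded plane,
tracing vessels by hand — does not scale to drug screens with hundreds of
wells imaged every few hours. `mpmimage` automates all three measurements
behind a small set of pipe-friendly functions returning tibbles, plus a
batch runner and a thin command-line wrapper, and ships a seeded
synthetic-fixture generator so every stage is testable without external
data. It is aimed at labs running 3D hydrogel co-culture models
(tube-formation, invasion, and coverage assays) on plate imagers.

## What it computes

**Coverage.** A Z-stack is reduced to a 2D projection (focus stacking,
min, max, median, or mean). Inside an automatically detected well boundary
(a superellipse |x/a|ⁿ + |y/b|ⁿ = 1 fit to Canny edges, with a centered
circular fallback), a two-component Gaussian mixture is fit to the pixel
intensities and the image is thresholded at

> μ_fg + λ·σ_fg

(the foreground component is the brighter one; λ is tunable — negative
values pass more pixels). Coverage is the thresholded area divided by the
well area.

**Invasion depth.** A binary classifier scores every Z-plane for the
presence of in-focus (invaded) cells; planes with probability ≥ 0.5 are
called invaded, and depth is the distance from the top plane to the deepest
invaded plane: `deepest_index × z_step_um`.

**Microvessels.** A refined 2D vesselness image is produced either by a
trained segmentation model on projections (tiled 512→320 prediction with
averaged overlaps, circularity/junction filtering, medial-axis centerline
weighting) or by Sato tubeness filtering of Z-stacks (unsharp masking,
max-projection, Canny-seeded region growing for background elimination).
A discrete-Morse ridge extractor — union-find persistence pairing over the
pixel grid, steepest-ascent arc tracing, cancellation of low-persistence
peaks — turns the ridges into an embedded graph ("Morse skeleton"), which
is pruned (leaf branches < 10 µm), smoothed, and summarized by persistent
homology: the barcode of the filtration f(x) = −dist(x, root) on the
shortest-path tree decomposes the network into branches, with each bar's
persistence equal to one branch length.

## Worked example

```r
library(mpmimage)

# a synthetic 256 px well with 25% of its area covered by cells
fx <- make_well_fixture(0.25, size = 256, seed = 7)
analyze_coverage(fx$image, fx$boundary, lambda = -3)
#> # A tibble: 1 × 7
#>   cell_area_px well_area_px fraction lambda mu_fg sigma_fg bimodal
#>          <int>        <int>    <dbl>  <dbl> <dbl>    <dbl> <lgl>
#> 1         9059        36280    0.250     -3  180.     12.0 TRUE
```

The mixture put the foreground at mean 180 and sd 12 (the generator's cell
intensity distribution); with λ = −3 the cutoff sits 3σ below the
foreground mean, and the recovered coverage fraction is 0.250 — the
requested 25% to three digits, with the pixel counts it came from.

```r
# a rendered vessel tree (truth: 5 branches, 499 µm) at SNR 5
vf <- make_vessel_fixture(n_branches = 7, size = 256, snr = 5, seed = 11)
zs <- zstack(list(vf$image), z_step_um = 1, pixel_size_um = 2)
vm <- sato_vesselness_2d(zs, scales = c(1, 2))
va <- analyze_vessels(vm, morse_params(), pixel_size_um = 2)
va$stats
#> # A tibble: 1 × 4
#>   branch_count total_length_um tree_length_um mean_branch_length_um
#>          <int>           <dbl>          <dbl>                 <dbl>
#> 1            4            466.           466.                  117.
```

The extracted skeleton has 4 branches (truth 5, within the ±1 the
acceptance suite demands) totalling 466 µm against a planted 499 µm
(−6.6%). `autoplot(va$graph, image = vf$image)` overlays the skeleton on
the image, `autoplot(va$barcode)` draws the branch-decomposition barcode.

```r
# confusion metrics with a guarded divide (positive class = invaded)
classification_metrics(confusion_counts(tp = 6, tn = 42, fp = 2, fn = 0))
#> # A tibble: 3 × 3
#>   metric      value defined
#>   <chr>       <dbl> <lgl>
#> 1 accuracy    0.96  TRUE
#> 2 sensitivity 1     TRUE
#> 3 specificity 0.955 TRUE
```

Batch runs map a plate directory onto one tidy metric table:

```r
cfg <- run_config("plates/exp1", pixel_size_um = 3.25, z_step_um = 4.25,
                  lambda = -3, save_intermediates = TRUE)
results <- run_batch(cfg)   # one row per well/time/channel/metric
```

or from a shell via `inst/cli/mpmimage coverage --input-dir plates/exp1 …`.

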