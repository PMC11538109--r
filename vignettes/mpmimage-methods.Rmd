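---
title: "Models and methods behind mpmimage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpmimage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mpmimage quantifies three phenotypic readouts of 3D cancer/endothelial
co-culture microphysiological models imaged as fluorescence Z-stacks on
non-confocal plate readers: **cell coverage area**, **cancer invasion
depth**, and **microvessel network structure**. This vignette explains the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic fixtures do and do not establish about real data.

```{r setup, message = FALSE}
library(mpmimage)
```

## Z-projections and the well boundary

A Z-stack is an ordered list of grayscale planes, top plane first, with a
user-supplied Z step (µm) and pixel size (µm/px). Acquisition metadata is
deliberately ignored: stack-depth conventions differ between instruments and
even between runs, so physical units are always explicit arguments.
`project_zstack()` offers the five standard reductions — per-pixel minimum,
maximum, median, mean, and focus stacking. Focus stacking selects, per
pixel, the plane with the largest local variance of the Laplacian in an
11×11 window (`focus_window`), matching the filter size plate-reader
software uses for its all-in-focus composites; it is the default projection
for coverage because cells sit at many depths in a 3D gel.

`detect_well_boundary()` delimits the analyzable region. Canny edges are
extracted (Gaussian σ 1.4; hysteresis thresholds from Otsu's split of the
non-maximum-suppressed gradient magnitudes, clipped at their 99.5th
percentile — without clipping a handful of very steep pixels can capture the
entire between-class variance and suppress all edges), and a superellipse
|x/a|ⁿ + |y/b|ⁿ = 1 is fit to the rim by Nelder–Mead least squares, started
from exponents 2 and 4. Three choices make the fit robust in practice. The
residual is the *radial* form (|dx/a|ⁿ + |dy/b|ⁿ)^(1/n) − 1 — the raw
implicit form has a degenerate valley (n → 0 with huge axes) that fits any
point set with near-zero residual. Only edges in the outer annulus
(radius ≥ 0.55·min(H, W)/2) enter the fit, with one outlier-trimmed refit,
so cell texture inside the well cannot drag the rim inward. And a soft
prior keeps the center near the image center, which plate-reader fields are
by construction; this resolves the arc ambiguity of partially detected
rims. The fit is rejected — and a centered circle of radius
`0.95·min(H, W)/2` used instead — when there are fewer than 100 edge
pixels, the residual exceeds the cap, or the solution leaves the frame. The
fallback always succeeds, so batch runs never stall on a well.

## Coverage: bimodal Gaussian-mixture thresholding

Inside the well boundary, pixel intensities of a labeled-cell projection are
bimodal: a dark hydrogel/plastic mode and a bright cell mode.
`fit_bimodal_gmm()` fits a two-component 1D Gaussian mixture by EM (via
mclust, whose hierarchical initialization makes the fit deterministic) on
the well-interior pixels only, so plastic outside the well cannot
contaminate the background component. The cutoff is

> threshold = µ_fg + λ·σ_fg

with the larger-mean component as foreground. λ = 0 places the cutoff at
the foreground mean; λ > 0 passes fewer pixels, λ < 0 more. The comparison
is inclusive (≥), which is immaterial for continuous intensities. Because a
symmetric foreground component has half its mass below its own mean, λ = 0
counts roughly half of the cell pixels; when the goal is the *full* cell
area of a well-separated foreground (the synthetic fixtures guarantee
|µ_fg − µ_bg| > 3σ), λ = −3 places the cutoff three foreground standard
deviations below µ_fg, which captures essentially all foreground while
excluding a 3σ-separated background. Coverage is the thresholded area
divided by the well interior area.

Two degenerate well states need care: a fully covered and a fully empty
well are *unimodal*, and forcing two components onto one mode splits it —
the threshold would then discard about half of a fully covered well. When
the one-component model beats the two-component model on BIC,
`analyze_coverage()` treats the well as homogeneous and decides between
all-covered and all-empty by the intensity coefficient of variation
(`cv_homogeneous`, default 0.15): fluorescence has a physical zero, so
bright signal-dominated wells have a much smaller relative spread than
dark noise-dominated ones. This rule uses ratio-scale information and is
therefore not invariant under intensity *offsets*; the standard bimodal
path is fully affine-covariant.

```{r coverage-example}
fx <- make_well_fixture(0.25, size = 256, seed = 7)
analyze_coverage(fx$image, fx$boundary, lambda = -3)
```

## Invasion depth: per-plane classification

Cancer cells seeded at the top of the construct invade downward; a plane
"shows invasion" when it contains enough in-focus cell area. What counts as
"enough" is never hard-coded — it is learned from labeled planes.
`train_invasion_classifier()` reduces each plane to six focus statistics
(variance of Laplacian, Tenengrad gradient energy, mean and 95th-percentile
local variance, high-frequency energy ratio, intensity spread), standardizes
them, and fits a single-hidden-layer neural network (nnet; width and
iteration budget configurable, weight decay 10⁻³). Training augments each
plane with seeded flips and rotations restricted to multiples of 90° so
labels are preserved exactly. A stratified hold-out split reports the
accuracy on unseen planes.

`classify_stack()` emits one probability per plane, top first, thresholded
inclusively at p ≥ 0.5 (the threshold is a parameter). The invasion depth is

> depth = (deepest invaded plane index, 0-based from the top) × z-step,

and 0 when no plane is invaded. The *deepest* invaded plane governs even
when shallower planes are called not-invaded: invading cells can sit in a
plane while the region above is out of focus. `classification_metrics()`
computes accuracy, sensitivity and specificity from confusion counts,
reporting `NA` with a `defined = FALSE` flag when a denominator is zero
rather than silently coercing to 0.

## Microvessel quantification

Vessel images reach graph extraction by one of two preparation paths
producing a 2D "vesselness" image whose bright ridges are vessel
centerlines.

**Learned path (projections).** A multiscale filter-bank pixel classifier
(`train_segmentation_model()`): per-pixel features are the Gaussian-smoothed
intensity, gradient magnitude, and tubeness response at a pyramid of scales
(one level per entry of `filters`), and a logistic unit is trained by
minibatch SGD with the schedule ⌊1500/batch⌋ training and ⌊500/batch⌋
validation steps per epoch, drawing `batch_size` images at random per step.
Normalization statistics come from the training split only and are frozen
into the model bundle. Pixel sampling per step is balanced between vessel
and background, which accelerates convergence but miscalibrates the
intercept; the standard case-control offset `log odds(π_true) −
log odds(π_sampled)` is applied once after training. A grid-search harness
(`grid_search_segmentation()`) selects the learning rate and filter counts
by validation Dice. Full-resolution images are predicted by overlapping
512×512 tiles resampled to the model input size (320 by default), with
overlapping predictions blended by pixelwise averaging
(`predict_tiled()`). The training-time augmentation pipeline
(`augment_sample()`) applies, with the stated probabilities, random
rotation (0.5), a random 512×512 crop (1.0), horizontal/vertical flips
(0.25 each), brightness/contrast jitter (0.7), exactly one of
multiplicative noise or blur-plus-noise (0.4 each, a seeded coin breaking
ties), and elastic deformation (0.85), then resamples to 320×320.
Geometric transforms are shared with the mask; photometric ones are not.

`refine_probability_map()` then (1) binarizes at p ≥ 0.5, (2) removes
blob-like components (circularity 4πA/P² > 0.8) and components whose 1-px
skeleton has no junction, (3) masks the probabilities, and (4) multiplies by
the medial-axis weight d_bg/(d_bg + d_medial) — 1 on the centerline, 0 at
the component border — so that ridge brightness coincides with the
centerline, which the ridge extractor assumes. The refinement never
amplifies: output ≤ input pixelwise.

**Sato path (Z-stacks).** Each plane is filtered with a Hessian-eigenvalue
tubeness operator (response σ²·max(−λ₂, 0) at scales `scales`, default
{1, 2, 4} px; finite differences use edge replication so the image frame
does not generate spurious responses), unsharp-masked (radius 5, amount 1),
and the stack reduced by max-intensity projection, preserving vessels at
any depth. Background is then eliminated with a binary mask: region growing
from seed pixels under the positive-gradient rule (an 8-connected neighbor
joins when its intensity is at least the boundary pixel's), morphological
closing, and removal of components that are blob-like (circularity > 0.8)
or smaller than `min_area_px`. Two robustness choices matter on noisy
inputs: the growth runs on a σ = 1.5 smoothed copy of the projection
(uphill growth on per-pixel noise zig-zags into the background), and the
seeds are the Canny edge pixels *plus* pixels above the 95th percentile of
the smoothed vesselness — a short dim segment can have no outline pixel
above the hysteresis threshold, and without a seed it would vanish from the
mask entirely. Scale selection follows the usual Hessian rule of thumb:
pick scales near the expected tube radius in pixels.

### Morse-skeleton extraction

`extract_morse_skeleton()` treats the vesselness image as a terrain and
returns its mountain-ridge network. The construction is discrete Morse
theory on the 8-connected pixel grid, with a deterministic total order
(value descending, linear pixel index ascending) acting as a symbolic
perturbation so plateaus and ties are handled identically on every run:

1. **Sweep.** Pixels are processed in descending order under a union-find.
   A pixel with no processed neighbor is a local maximum (a peak). A pixel
   whose processed neighbors span two components is a *merge saddle*: the
   younger peak (lower value) is paired with it, and its persistence is
   peak height minus saddle height.
2. **Arcs.** For every saddle, ridge arcs are traced by steepest ascent
   (highest-in-order neighbor) from the saddle's two entry neighbors to a
   maximum on each side. Ascent strictly climbs the order, so it
   terminates; deterministic ties make the geometry reproducible. The merge
   arcs form a spanning tree of the peaks in each component.
3. **Cancellation.** (Peak, saddle) pairs below the persistence cutoff are
   cancelled by iteratively deleting sub-cutoff *leaf* peaks together with
   their pairing arc — exactly the pairwise cancellation with arc
   rerouting: a cancelled peak interior to a ridge path simply becomes a
   regular through-point, while noise spurs hanging off the ridge are
   removed. Two significance cuts protect structure: a peak survives by
   persistence ≥ cutoff *or* by height ≥ min + `value_floor_frac`·range
   (default 0.25). The second cut matters because the ends of a ridge of
   roughly constant height have low persistence but full height; without it
   a uniform tube would collapse to a single peak.
4. **Assembly.** Surviving arcs are united as a subgraph of the pixel grid
   (all steps horizontal, vertical, or 45°); overlapping ascent paths
   coincide exactly, so shared ridge segments merge. Maximal paths between
   junction/leaf pixels become branches of the returned `embedded_graph`.

The persistence cutoff defaults to `max(2·mad(image), 10⁻³·range)` — twice
the robust noise scale, floored so the exactly-equal plateau peaks of
masked synthetic backgrounds cancel. Saddles lying on the exact
global-minimum plateau never bridge components: ridges should connect peaks
across *dim* regions, not across masked-out background. Saddles that close
a cycle (detected by ring-connectivity of the processed neighborhood) are
traced only when `keep_loops = TRUE`: on noisy ridge bands every ring-split
saddle would add a spurious cycle that no leaf pruning can remove, while
with loops off a genuine cycle is still recovered except for a short gap at
its dimmest saddle. This trade-off is acceptable for branch statistics and
is the default.

`prune_and_filter()` removes leaf branches shorter than `min_branch_um`
(default 10 µm — shorter branches are usually rasterization or segmentation
noise), re-merges the degree-2 chains this exposes, and repeats to a fixed
point; optionally only the component of largest total length is kept
(`analyze_vessels()` enables this by default, appropriate whenever the well
contains one vessel network of interest and isolated bright objects are
debris). After pruning, `analyze_vessels()` extends each leaf branch along
its end direction until the vesselness falls below half the leaf-end value:
ridge arcs end at the last significant maximum, a few pixels short of where
the tube actually stops, and the half-maximum point is the standard
definition of where a peaked profile ends. Finally
`smooth_branches()` replaces interior polyline points by a centered moving
average (window 5 by default, truncated near the ends) with junctions and
leaves fixed: grid-aligned staircases overestimate oblique lengths, and
smoothing brings a unit staircase toward its chord without changing
topology.

### Branch decomposition by persistent homology

Statistics come from the barcode of the filtration f(x) = −dist(x, root) on
the shortest-path tree (`analyze_topology()`):

* the **root** is the network center — the vertex of minimum geodesic
  eccentricity in the largest component, ties to the smallest id;
* the **shortest-path tree** uses length-weighted geodesics, predecessor
  ties broken by smallest id, making cyclic networks tree-like before
  barcoding;
* each leaf spawns a bar born at −dist(leaf, root); when two growing
  branches merge, the younger bar dies (elder rule, ties by leaf id), and
  the deepest leaf's bar dies at 0.

Each bar's persistence is one branch length, so persistences sum *exactly*
to the tree length — a conservation law the tests verify to 10⁻⁹ relative
tolerance on random trees. `summarize_network()` reports the branch count
(number of bars), the mean branch length (mean persistence), and both the
full graph length and the tree length; the two coincide for trees and the
column labels keep them distinct for cyclic networks.

```{r vessels-example}
fx <- make_vessel_fixture(n_branches = 7, size = 256, snr = 5, seed = 11)
zs <- zstack(list(fx$image), z_step_um = 1, pixel_size_um = 2)
vm <- sato_vesselness_2d(zs, scales = c(1, 2))
va <- analyze_vessels(vm, morse_params(), pixel_size_um = 2,
                      presmooth_sigma = 0)
va$stats
```

## Synthetic fixtures: what they establish, and what they do not

`make_well_fixture()`, `make_invasion_fixture()` and `make_vessel_fixture()`
generate seeded, bit-reproducible images with exact ground truth:

* **Wells** (512×512 default): a disk or superellipse well on dark plastic;
  the requested coverage fraction is realized exactly by thresholding a
  smooth random field at the matching quantile; foreground N(180, 12²) vs
  background N(25, 5²) honours the 3σ separability rule.
* **Invasion stacks** (10 planes of 64×64, 10 µm steps): planes at or above
  the true deepest index carry sharp speckle, deeper planes the same
  pattern defocused by a σ = 4 blur plus sensor noise.
* **Vessel trees** (256×256 at 2 µm/px): a trunk plus pairs of children
  with bounded angle jitter, rejection-resampled so non-adjacent branches
  keep a two-tube-width clearance; tubes rendered with Gaussian
  cross-section (FWHM = tube width, 4–8 px) and additive Gaussian noise at
  SNR 5; truth graphs contract degree-2 nodes so the recorded branch count
  is the observable branch decomposition. Straight-tube unit fixtures are
  rendered oblique: an axis-aligned constant-amplitude tube is an exact
  intensity plateau, a measure-zero degeneracy real images never exhibit.

Passing on these fixtures shows the estimators recover known geometry and
intensity structure under Gaussian noise and defocus blur. It does *not*
establish performance on real hydrogel images, which add autofluorescence
gradients, touching and overlapping vessels, debris, uneven illumination,
and annotation ambiguity; the published comparisons against manual
measurements cover that ground. In particular the 2D pipeline cannot
separate vessel branches that cross in Z — only the most prominent branch
survives the projection — and fixture trees are planted non-overlapping by
construction.

## Problem sizes and numerical notes

The test and acceptance suites run at desk scale, chosen so the full suite
completes in minutes on one CPU: 256 px vessel fixtures (25 seeds), 200
labeled invasion planes and 50 evaluation stacks, 30/10 segmentation splits
of 96 px tiles with 5 epochs at learning rate 0.01 (a linear filter-bank
model tolerates, and needs, a larger step than the 0.001 reference for a
deep network). Marching-squares perimeters are calibrated by a factor 0.98
so an ideal rasterized disk has circularity ≈ 1 while axis-aligned
rectangles stay near exact. Degenerate inputs have defined behavior
throughout: constant images yield empty graphs or explicit degenerate-input
errors, empty barcodes yield zeroed statistics, and undefined metric ratios
are flagged rather than zeroed.
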