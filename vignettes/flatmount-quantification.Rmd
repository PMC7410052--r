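---
title: "Quantifying retinal flat-mount vasculature with flatquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal flat-mount vasculature with flatquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(flatquant)
```

## The measurement problem

In the oxygen-induced retinopathy (OIR) model, hyperoxia closes arterial
side branches, starves downstream capillaries of flow, and drives
endothelial cells (ECs) to apoptose and vacate their vessels. The vessel's
collagen IV basement membrane outlives its endothelium, so a flat-mounted
retina stained for both an endothelial marker (PECAM1/CD31) and collagen IV
shows regressed segments as collagen IV-positive, PECAM1-negative
"sleeves". On return to room air, hypoxia (read out with pimonidazole)
drives revascularization, and in the pathological case, neovascular tufts
— bright, globular collagen IV-positive lesions.

`flatquant` turns the standard flat-mount readouts of this model into
deterministic, scriptable measurements over calibrated multi-channel 2D
projections:

* **vessel area fraction** — vessel mask area over region area;
* **regression ratio** — the skeleton-length fraction of the collagen IV
  network lacking (or retaining) EC signal, with an ICAM2 variant for
  lumen integrity;
* **fragmentation index** — independent vessel skeletons per mm²;
* **branch-point density** — skeleton junctions per mm²;
* **mean vessel width** — vessel area over centerline length;
* **vaso-obliterated fraction** — avascular area after morphological
  closing at the capillary-mesh scale;
* **side-branch perfusion census** — perfused / attached / disrupted /
  detached calls from lectin, ICAM2 and collagen IV continuity,
  normalized to artery length;
* **cell counts** — FLI1/ERG nucleus particles, pHH3⁺ proliferating
  fraction, active-caspase-3⁺ apoptotic ECs enclosed by collagen IV;
* **hypoxic-area fraction** and **neovascular tuft area**;
* a **4-parameter logistic** standard curve for ELISA quantification.

Because no retinal image data are deposited with such studies, every
metric is validated against a synthetic flat-mount generator that plants
known ground truth. This vignette explains the models, the defaults, and
the numerical choices.

## The synthetic flat-mount model

### Network geometry

`generate_plexus()` builds a jittered honeycomb mesh. Capillary networks
are approximately 3-valent, and a honeycomb is the simplest planar
3-valent tessellation with controllable density. The one free parameter is
`capillary_density` (mesh edges per µm²); the honeycomb edge length is
then `sqrt(2 / (sqrt(3) * density))`, so the density-implied total vessel
length in a field of area `A` is `A * sqrt(2 * density / sqrt(3))` — an
analytic target the generator hits within a few percent (boundary trimming
loses a little, jitter adds a little). The default density of 0.002 gives
24 µm edges and ~40 µm capillary spacing, which is the right order for a
mouse superficial plexus; the paper-style images provide no quantitative
geometry, so these defaults are chosen for testability, not anatomical
fidelity. Radial arteries are walked greedily from the central (optic
nerve head) node along evenly spaced directions and widened to 12 µm;
every non-artery edge leaving an interior artery node is a side branch.

```{r plexus}
net <- generate_plexus(600, capillary_density = 0.002, n_arteries = 4,
                       rng_seed = 1)
net
```

### Perturbations with ground truth

`apply_regression()` removes endothelium (`ec_present = FALSE`) from edges
totalling a target fraction of length. `random-edge` mode shuffles edges;
`cluster-contraction` mode emulates what apoptosis blockade produces —
surviving ECs contracted into isolated islands. It grows `n_clusters`
node-disjoint connected regions from seed nodes (pairwise ≥ 3 hops apart)
in round-robin until the retained length meets the budget; every edge not
interior to one region regresses. Cross-region edges always regress, so
the EC subgraph has exactly `n_clusters` components — the planted truth
for the fragmentation metric. The reported ground truth is always
recomputed from the final edge flags, never from the request.

`apply_perfusion_loss()` closes side branches, recomputes perfusion as
reachability from the artery root without the closed edges, and assigns
each closed branch a lumen class: `attached` (ICAM2 rendered intact),
`disrupted` (two sub-tolerance ICAM2 gaps within ~20 µm of the junction,
an operational stand-in for "abnormal ICAM2 morphology"), or `detached`
(one supra-tolerance gap, collagen IV continuous). Gaps are placed just
beyond the parent artery's half-width so they are geometrically visible
outside the artery ribbon.

### Rendering

`render_flatmount()` rasterizes edges as constant-width capsule ribbons
into the canonical channels — collagen IV covers all edges, PECAM1 only
EC-positive edges, ICAM2 with the class-specific junction gaps, lectin
only perfused EC edges — then adds FLI1 nuclei (non-overlapping ellipses,
default 64 px² ≈ an 8 µm EC nucleus; a configurable subset co-rendered in
pHH3, apoptotic cells in caspase-3), a pimonidazole field, tufts, PSF
blur, Gaussian noise, salt noise, and a 16-bit quantization. Nuclei never
overlap by construction (minimum centre spacing of two nucleus diameters)
so counting validation is exact.

The hypoxia field is a sum of a few broad Gaussian bumps thresholded at
the intensity quantile that makes the supra-threshold area over the
central region equal the requested fraction — only the area fraction is
consumed downstream, so the field's shape is free and the truth is exact
to pixel resolution. Tufts are wobbled discs (solidity ≈ 0.9) rendered at
full scale on the collagen IV channel, whose vessel gain is kept at 0.4 so
the lesions are "bright and globular" relative to normal vessels by a
factor above the default detection threshold of 2× the vessel median.

All randomness passes through one seeded generator per call
(`withr::with_seed`); the same seed and configuration reproduce images
bit for bit.

### What the generator does not emulate

Uneven illumination, staining gradients, out-of-focus light from other
plexus layers, touching nuclei, vessel-width variation along segments,
and genuinely tortuous capillary paths. Passing the recovery suite
therefore demonstrates that the *measurement chain* is unbiased on
geometry it can represent, not that segmentation will be this clean on
real micrographs; on real data the pixel classifier and manual threshold
override exist precisely because Otsu on a single channel may not be
sufficient.

## Segmentation

Recipes mirror the ImageJ conventions the field uses: a disc median
filter ("median (2 pixels)" = radius 2), `despeckle` (3×3 median), and a
threshold. The default threshold is Otsu on a 256-bin histogram over the
observed range, replacing per-image manual adjustment so the pipeline is
reproducible; a manual value can be given and is recorded in the mask's
recipe provenance either way. Thresholding uses strict `>` with ties to
background. The interactive trainable-segmentation step is replaced by a
random-forest pixel classifier over raw intensity, Gaussian blurs at
scales {1, 2, 4} px, Sobel gradient magnitude and Laplacian — the
smallest feature set that cleanly separates ribbon vessels from
background on the synthetic fixtures. The forest size is kept odd so
binary majority votes cannot tie, which together with a fixed seed makes
classification fully deterministic.

## Skeleton measures

Masks are thinned to 1-px, 8-connected skeletons (Zhang–Suen parallel
thinning followed by a sequential simple-point pruning pass using the
Yokoi connectivity number; the pruning removes the staircase run-overlap
pixels the parallel scheme must leave, which would otherwise inflate
length by up to 30% for ribbons near 15–25°). A mask component that
thinning would erase entirely keeps its innermost pixel so small
fragments stay countable. Geodesic length sums pixel steps — `pixel_size`
per axial step, `sqrt(2) * pixel_size` per diagonal — with each adjacent
pair counted once. This digital metric overestimates true Euclidean
length by up to ~8% at intermediate angles; the bias largely cancels in
the regression *ratio*, whose numerator and denominator share it.

Fragmentation counts 8-connected skeleton components at least
`min_length_um` (default 5 µm) long, excluding single-pixel noise
skeletons; the threshold is exposed because the original workflow does
not state any exclusion. Branch points are skeleton pixels of degree ≥ 3
with adjacent branch pixels merged into one junction, preventing thinning
artifacts from double-counting an anatomical branch point.

### The regression ratio's end correction

The regressing mask (collagen IV AND NOT dilated-PECAM1) is skeletonized
independently of the collagen IV mask, mirroring the mask-subtraction
recipe. Two systematic losses shorten the regressing skeleton relative to
planted length: thinning erodes each free mask end by about the local
half-width, and the subtraction itself cuts each sleeve fragment back by
the EC cap plus the 1-px registration dilation. Both are measurable from
the masks, so each skeleton endpoint adds back its distance-transform
radius, plus the EC-side cap and dilation when the endpoint abuts the EC
mask. With the correction the planted-fraction ladder is recovered within
about ±0.015 at every point with unit slope; without it, errors reach
−0.07 at low fractions where the regressing mask is most fragmented.

## Perfusion census

Side-branch detection traces the collagen IV skeleton as a graph, labels
as "artery" every path lying ≥ 60% inside a 3-px corridor around the
supplied centerline, and takes non-artery paths leaving artery junctions
as candidate branches; candidates nearly parallel to the local centerline
tangent (|cos| > 0.9) are rejected as artery continuations (the skeleton
runs on past the end of an annotated centerline). Classification walks
the first 50 µm of the branch: lectin continuity is tested in a 1-px
dilated neighbourhood of the path; ICAM2 and collagen IV gaps are
measured at skeleton resolution so sub-tolerance gaps a few pixels wide
remain detectable. The default gap tolerance of 5 µm operationalizes
"continuous overlap", for which the manual protocol states no tolerance;
the 50 µm window reflects that the taxonomy concerns the junction region,
not the whole downstream tree. On noise-free renders the planted-class
confusion matrix is fully diagonal for gaps at twice and half tolerance.

## Cells, hypoxia, tufts

Nucleus counting follows the particle recipe exactly: median(2),
despeckle, threshold, 8-connected labeling, keep particles strictly
greater than 20 px² whose centroid lies on the 2-px-dilated vessel mask.
Note the two filters erode particles: a planted ellipse must be ~60 px²
or more to survive above the 20 px² floor, which is why the generator's
default nucleus is 64 px². Proliferation is the fraction of nuclei whose
mean pHH3 intensity exceeds a threshold (Otsu over the per-nucleus means
by default). Apoptotic ECs are caspase-3 particles overlapping the EC
mask whose centroid falls inside the 1-px-closed collagen IV mask
("enclosed by collagen IV"), per mm² of region.

The hypoxic fraction applies a radius-20 disc median before thresholding;
with the default Otsu a degenerate (blank) channel yields an empty mask.
Tuft detection thresholds collagen IV at `intensity_factor` (2.0) times
the median intensity over the vessel mask, then keeps components with
area ≥ 100 µm² and solidity ≥ 0.85 — "bright, globular" made operational;
branched vessel networks fail the solidity test and background noise
fails the area test, giving zero lesion area on tuft-free fixtures.

## 4PL standard curve

`fit_4pl()` fits `y = d + (a − d) / (1 + (x/c)^b)` (Hill form; `a` the
zero-dose response, `d` saturation, `c` the EC50, `b` the slope) by
Levenberg–Marquardt with the deterministic start `a = min y`, `d = max y`,
`c` = geometric mid of the positive standards, `b = 1`, and no weighting.
`invert_4pl()` applies the closed-form inverse and flags back-calculated
concentrations outside the standard range. Noise-free round trips recover
parameters to 10⁻⁴ relative and invert∘evaluate to 10⁻⁶.

```{r fourpl}
x <- c(7.8, 15.6, 31.2, 62.5, 125, 250, 500, 1000)
std <- data.frame(concentration = x,
                  response = 2 + (0.1 - 2) / (1 + (x / 50)^1.2))
fit <- fit_4pl(std)
tidy(fit)
invert_4pl(fit, 1.05)
```

## Orchestration and reproducibility

`run_pipeline()` drives simulate → segment → measure → report from one
validated configuration (unknown keys are rejected before any work;
missing required fields are named). Outputs are a tidy metrics CSV with a
parameter-hash provenance column, a side-branch call table, region masks
and a JSON manifest of config, versions and seeds; repeated runs with the
same seed are byte-identical. A thin command-line wrapper with
`simulate` / `segment` / `measure` / `report` / `all` subcommands is
installed under `inst/cli/flatquant`.

Problem sizes throughout the validation suite — 400–600 µm fields at
1 µm/px, 10–20 images per property — are chosen so the whole recovery
suite re-runs in minutes on one CPU while every planted structure is
still several pixels wide.

## Known limitations

* Touching or overlapping nuclei are not split; real FLI1 fields with
  dense nuclei will undercount (the generator's non-overlap guarantee is
  explicitly not a property of real data).
* The digital length metric's angle-dependent bias (≤ 8%) is inherited
  by absolute lengths, though not by length ratios.
* Artery centerlines are inputs, not inferred from morphology.
* Central/peripheral demarcation on real retinas must be supplied as
  masks or annulus radii; there is no algorithmic definition.
* The ESM1/ANG2-style "expression" comparisons are supported only by the
  generic `mean_intensity_in_mask()` readout, as the original
  quantification protocol for those is not specified beyond intensity.
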