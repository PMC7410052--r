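# flatquant

Reproducible quantification of retinal flat-mount vasculature images, as
used in oxygen-induced retinopathy (OIR) studies of vessel regression and
revascularization.

## The problem

In the OIR model, hyperoxia closes arterial side branches, deprives
downstream capillaries of flow, and endothelial cells (ECs) die or
withdraw from their vessels. Because the collagen IV basement membrane
persists as an empty "sleeve" after EC loss, a flat-mounted retina
co-stained for an endothelial marker (PECAM1/CD31) and collagen IV
records the history of regression; lectin perfusion, ICAM2, pimonidazole
and nuclear/proliferation/apoptosis markers complete the standard panel.
These readouts are usually quantified by hand in ImageJ. `flatquant`
makes them scriptable, calibrated and deterministic:

- **Vessel area fraction** per region: `area(vessel ∩ region) / area(region)`.
- **Regression ratio**: skeletonize the collagen IV mask and the
  subtraction mask (collagen IV ∧ ¬PECAM1) independently and report the
  length ratio `L(regressing)/L(coliv)` (and its complement, the
  PECAM1/collagen IV ratio). An ICAM2 variant measures lumen loss.
- **Fragmentation index**: number of separate, independent vessel
  skeletons per mm² (8-connected components, ≥ 5 µm by default).
- **Branch-point density**: merged skeleton junctions (degree ≥ 3) per mm².
- **Mean vessel width**: total vessel area / total centerline length.
- **Vaso-obliterated fraction**: avascular area after morphological
  closing at the capillary-mesh scale (25 µm default).
- **Side-branch perfusion census**: each arterial side branch is called
  `perfused`, `attached`, `disrupted` or `detached` from lectin/ICAM2/
  collagen IV continuity along its first 50 µm, and perfused branches are
  normalized to artery length.
- **Cell counts**: FLI1/ERG nucleus particles (> 20 px² after median and
  despeckle filters), pHH3⁺ proliferating fraction, active-caspase-3⁺
  apoptotic ECs enclosed by collagen IV, per mm².
- **Hypoxic-area fraction** (radius-20 median, threshold, per region) and
  **neovascular tuft area** (bright, globular collagen IV⁺ components).
- **4PL ELISA standard curve**: `y = d + (a − d)/(1 + (x/c)^b)` with
  closed-form inversion, for VEGFA-style quantification.

No retinal image data are deposited with such studies, so validation is
by ground-truth recovery: a synthetic flat-mount generator plants a
jittered honeycomb plexus with radial arteries, applies OIR-like
perturbations (clustered EC loss, side-branch closure with downstream
perfusion loss, hypoxia fields, tufts, nuclei) with known parameters,
renders noisy multi-channel images, and every metric is checked against
the planted truth.

## Worked example

Simulate a half-regressed retina fragmented into 12 EC clusters, segment
it with the standard recipe, and measure:

```r
library(flatquant)

net <- generate_plexus(field_size_um = 600, capillary_density = 0.002,
                       n_arteries = 4, rng_seed = 1)
#> <vessel_network> 470 nodes, 666 edges (16079 um total), 4 arteries, 61 side branches

rg  <- apply_regression(net, target_fraction = 0.5,
                        mode = "cluster-contraction", n_clusters = 12,
                        rng_seed = 2)
sim <- render_flatmount(rg$network, extras = list(n_nuclei = 40),
                        config = render_config(rng_seed = 3))
#> truth: regression 0.499, 12 EC component(s), 40 nuclei, hypoxic 0.400

pecam <- run_recipe(sim$image$channels$pecam,
                    list(list(step = "median_filter", radius = 2),
                         list(step = "despeckle"),
                         list(step = "threshold", method = "otsu")))
coliv <- binarize(sim$image$channels$coliv, "otsu")

regression_ratio(pecam, coliv, pixel_size = 1)
#> # A tibble: 1 × 4
#>   ec_over_coliv regressing_over_coliv coliv_length_um regressing_length_um
#> 1         0.512                 0.488          17040.                8318.

field <- sim$regions$regions$field
fragmentation_index(pecam, field, pixel_size = 1)   # skeletons per mm^2
#> 33.33333                                           # = 12 components / 0.36 mm^2
mean_vessel_width(pecam, pixel_size = 1)
#> 6.45614                                            # um; capillaries rendered at 6 um
count_nuclei(sim$image$channels$fli1, pecam, pixel_size = 1)$count
#> 40
```

The measured regressing fraction (0.488) recovers the planted 0.499; the
fragmentation count recovers the planted 12 clusters exactly; the width
and nucleus count match the rendered geometry.

The same measurements run end to end from a YAML config with
`run_pipeline()` (or the `inst/cli/flatquant` script), writing a tidy
metrics CSV, side-branch call table and JSON manifest; fixed seeds give
byte-identical outputs.

## Package layout

- `R/synthetic-network.R`, `R/synthetic-render.R` — generator: plexus,
  regression, perfusion loss, rendering with ground truth.
- `R/imaging-io.R` — calibrated multi-channel TIFF I/O, regions, areas.
- `R/segmentation.R` — filters, thresholds, recipes, pixel classifier.
- `R/skeleton.R`, `src/flatquant.cpp` — thinning, components, lengths,
  branch points (C++ kernels).
- `R/vessel-metrics.R`, `R/perfusion.R`, `R/cells-hypoxia.R` — the
  biological metrics.
- `R/quant-stats.R` — 4PL curve, tidiers, report assembly.
- `R/pipeline.R`, `inst/cli/flatquant` — config-driven orchestration.
- `vignettes/flatmount-quantification.Rmd` — models, defaults, numerical
  choices, limitations.
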