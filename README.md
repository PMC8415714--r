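# fruitpore

Pore microstructure analysis of X-ray micro-CT fruit volumes in R.

Physiological disorders of pome fruit — cork spot in pear being a prime
example — change the tissue's intercellular air space long before visible
symptoms appear: pores grow, multiply and interconnect, most strongly in
the outer mesocarp. Micro-CT sees this directly (air attenuates X-rays far
less than hydrated tissue, so pores are dark voxels in a bright flesh
matrix). `fruitpore` turns a reconstructed grayscale volume into the
standard morphometric read-outs used to compare healthy and disordered
fruit, and ships a synthetic phantom generator with exact ground truth so
that the whole chain is testable without scanner data.

## What it computes

Given a volume (multi-page TIFF, a directory of numbered TIFF slices, or
MHD + raw):

* **Fruit mask** — Otsu threshold, largest 26-connected bright component,
  3D cavity filling (`compute_fruit_mask`).
* **Phase segmentation** — global threshold at the deep valley of the
  masked gray-level histogram; voxels with intensity `< T` are pore
  (`compute_histogram`, `find_valley_threshold`, `segment_phases`).
* **Pore morphometry** — 26-connected pore labeling; per-pore volume and
  equivalent-sphere diameter `d_eq = (6V/π)^(1/3)`; porosity (% pore
  voxels) of any region; per-slice axial porosity profiles (calyx → stem);
  100-µm-class size histograms; pore number density per mm³
  (`label_pores`, `build_pore_table`, `porosity`, `porosity_profile`,
  `pore_size_histogram`, `pore_number_density`).
* **Pore network** — topology-preserving 3D thinning to a filar
  centerline; exact Euclidean distance map; decomposition into pore-body
  nodes and throat edges with throat length/diameter, pore length
  (body diameter) and coordination numbers
  (`skeletonize`, `distance_map`, `extract_network`, `network_stats`).
* **Regions** — mesocarp partitioned into LRA / MRA / HRA risk zones by
  normalized core-to-skin depth; grayscale core extraction with a
  geometric fallback when the core has no contrast; core volume, solidity
  and sphericity (`partition_mesocarp`, `extract_core`,
  `core_shape_metrics`).
* **Statistics** — arcsine-transformed Welch comparisons for
  percentage-valued morphometrics (`arcsine_transform`, `compare_groups`).
* **Phantoms** — fruit-shaped or slab phantoms with configurable porosity
  targets, diameter distributions, axial placement profiles, core and
  noise; tube phantoms with analytic centerlines
  (`phantom_spec`, `phantom_preset`, `generate_phantom`,
  `generate_tube_phantom`).

`run_pipeline()` composes all stages from a `run_config()` (serializable
to YAML) into a reproducible JSON/CSV report; a thin command-line wrapper
lives at `inst/cli/fruitpore.R`.

## Worked example

Generate a cork-spotted whole-fruit phantom (porosity target 9.37%,
U-shaped axial pore placement, no core contrast) on a 128³ grid and run the
full pipeline:

```r
library(fruitpore)
cfg <- run_config(
  input  = list(preset = "corkspot_whole", seed = 1),
  params = list(grid_shape = c(128, 128, 128))
)
report <- run_pipeline(cfg)
print(report)
#> <run_report> 2026-09-28T10:22:31+0000
#>  stages: load, mask, segmentation, morphometry, skeleton, regions
#>  threshold 67.50 (valley)
#>  porosity 9.37%, 843 pores, mean d_eq 319 um
#>  network: 1552 nodes, 850 edges, avg coordination 1.10 (max 12)
report$truth_comparison$true_porosity_percent
#> [1] 9.365312
report$regions$core_source
#> [1] "fallback_ellipsoid"
```

Reading the numbers: the valley threshold landed at 67.5 between the dark
pore mode (mean 30) and bright tissue mode (mean 160); measured porosity
9.37% recovers the generator's ground truth (9.365%) to within a few
thousandths of a point; the disordered fruit's core has no grayscale
contrast, so the report flags the geometric fallback core rather than
failing. The network section summarizes the pore graph: average
coordination 1.10 with a maximum of 12 reflects the highly branched void
space that distinguishes disordered from healthy tissue (whose isolated
round voids give coordination 0).

Comparing groups the way percentage morphometrics are compared:

```r
healthy <- c(3.1, 3.6, 3.9, 3.4, 3.7)   # porosity %, five fruit
cork    <- c(8.9, 9.8, 10.1, 9.0, 9.3)
compare_groups(cork, healthy)$p_value   # Welch t on arcsine(sqrt(p)) scale
```

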