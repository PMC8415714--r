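---
title: "Quantifying fruit pore microstructure from micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fruit pore microstructure from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cork spot is a preharvest physiological disorder of pear in which patches of
flesh turn necrotic and lignified, most often in the outer mesocarp near the
calyx end. The tissue change has a structural signature long before visible
symptoms: the intercellular air space (the *pore* phase) of disordered flesh
is larger, denser and far more interconnected than in healthy fruit. X-ray
micro-CT resolves this non-destructively — air attenuates X-rays far less
than hydrated tissue, so pores appear as dark voxels inside a bright flesh
matrix — and a standard analysis chain turns a reconstructed grayscale
volume into a small set of morphometric numbers: porosity, pore size
distributions, axial porosity profiles, and the geometry of the pore
*network* (throat lengths and diameters, pore-body sizes, coordination
numbers).

`fruitpore` implements that chain as composable, tested R functions:

1. **fruit masking** — separate fruit from surrounding air,
2. **phase segmentation** — a global grayscale threshold at the deep valley
   of the masked histogram splits tissue from pores,
3. **pore morphometry** — 3D connected-component labeling, equivalent-sphere
   diameters, porosity and per-slice axial profiles,
4. **skeleton network** — topology-preserving thinning to a filar
   centerline, decomposed via the Euclidean distance map into pore bodies
   (nodes) and throats (edges),
5. **regions** — mesocarp risk zones by normalized depth and fruit-core
   extraction with shape metrics,
6. **group statistics** — arcsine-transformed Welch comparisons of
   percentage-valued measurements.

Because scanner data of this kind is rarely deposited, the package ships a
**synthetic phantom generator** whose ground truth (exact phase map, pore
table, centerlines) exercises every stage; all package tests and the
bundled acceptance script run on phantoms alone.

## Segmentation model and its assumptions

The grayscale model is bimodal-by-phase: pore voxels (air) form a dark mode,
tissue a bright mode, with approximately Gaussian spread from scanner noise.
Air outside the fruit is as dark as the pores, so the histogram must be
computed *inside a fruit mask*. The mask is Otsu's threshold on the full
volume, followed by the largest 26-connected bright component and 3D filling
of enclosed cavities — internal pores and the core belong to the fruit.

`find_valley_threshold()` smooths the masked histogram with a centered
moving average (default window 9 bins, chosen to suppress counting noise in
the valley without merging modes), finds the two highest local maxima with
at least 0.5% of the main mode's mass (tail wiggles are not phases), and
puts the threshold at the center of the lowest bin strictly between them —
the "obvious deep valley" of a two-phase histogram. Ties take the lowest
bin; a unimodal histogram falls back to Otsu's threshold and reports
`source = "otsu"`. Classification is **strict**: intensity `< T` is pore.
The strict comparison admits fractional thresholds (such as 69.7 on an
8-bit scale) without re-quantizing the data. Thresholds are found per
volume, never shared between fruits, since illumination and penetration
differ between scans.

16-bit reconstructions are windowed to 8 bits with half-away-from-zero
rounding; the default window is the observed intensity range, which is
parameter-free and preserves the histogram shape the valley detector needs.
`map_threshold_to_8bit()` maps a threshold through the same window so that
porosity is invariant under conversion (it targets the midpoint between the
8-bit images of the two straddling gray levels, because the naive linear
image of the threshold can be crossed by rounding).

## Pore morphometry conventions

* Connectivity is **26** (face, edge or corner) by default — two pore voxels
  touching even at a corner belong to one pore. 6-connectivity is retained
  as an option for sensitivity checks.
* The equivalent diameter of a pore of volume $V$ is the diameter of the
  sphere of equal volume, $d_{eq} = (6V/\pi)^{1/3}$.
* Porosity of a region is pore voxels over region voxels, in percent.
  Per-slice porosity runs calyx end (slice 1) to stem end; slices with an
  empty fruit cross-section are flagged `NA`, not zero-filled.
* Size histograms use 100-µm classes centered at 100, 200, … 3000 µm with
  nearest-center assignment, the labeling conventionally used for
  whole-fruit pore histograms; diameters at or beyond the top class land in
  the top class.
* "Mean pore diameter" is the unweighted mean of $d_{eq}$ over pores; a
  volume-weighted mean is also reported by the pipeline since the two can
  differ strongly for wide size distributions.
* No minimum-pore-size filter is applied by default (`min_voxels = 1`);
  how scanner noise should be pruned is data-dependent and left to the
  caller.

Coordinates are 0-based voxel indices; physical positions use the
voxel-center convention, $(i + 0.5)\,h$ for voxel size $h$.

## Skeleton network

The pore phase is reduced to a one-voxel-thick curve skeleton by parallel
3D thinning with sequential re-checking: a voxel may be deleted only if it
is *simple* for the (26, 6) digital topology — exactly one 26-component of
object voxels in its 26-neighborhood and exactly one 6-component of
background voxels among its 18-neighbors adjacent to it — so connected
components, cavities and tunnels are preserved exactly. Curve endpoints
(one object neighbor) are kept, so tubular structures retain their length.
Border directions are stripped one at a time (six subiterations per pass)
to keep the skeleton centered.

The **Euclidean distance map** (exact, center-to-center, via the separable
squared-distance transform) supplies all radii. Skeleton voxels with one
26-neighbor are endpoints, two are path voxels, three or more junction
voxels; 26-adjacent junction voxels merge into one node at their centroid.
Traced paths between nodes are edges. Two refinements follow:

* **Spur pruning** — endpoint-terminated edges shorter than `spur_min_um`
  (default two voxels) are removed, iterating to a fixed point. This is the
  minimal denoising of a raw voxel skeleton.
* **Endpoint retraction** — digital thinning overruns rounded pore ends:
  the medial axis of a hemispherical cap is a point, but the discrete curve
  runs on to the cap surface where the distance map falls to one voxel. A
  tip is retracted while the distance map climbs consistently inward (at
  least 0.25 of the step length per step). Constant-radius channels show no
  such climb and are untouched. A component whose entire skeleton is
  shorter than its own largest inscribed-sphere radius is the remnant of a
  single round void and collapses to one isolated node.

Network semantics (fixed conventions, since "pore" versus "throat" length
cannot be disambiguated from summary tables alone): a **throat** is a graph
edge; its diameter is twice the minimum distance-map value over the path
interior, its length the path length minus the two incident body radii
(floored at zero). A **pore body** is a node with radius equal to the
distance-map value at the node (the largest over a junction cluster), and
"pore length" is its diameter $2r$. **Coordination** is the number of
incident edges, averaged over *all* nodes including isolated ones — a pore
space of disconnected round voids therefore has average and largest
coordination 0, which is exactly how a healthy, poorly-connected fruit
presents.

## Regions and core

The mesocarp is partitioned by normalized depth
$u = d_{core}/(d_{core} + d_{skin})$, the fraction of the way from the core
surface to the skin. Default boundaries at equal thirds give LRA (inner),
MRA (middle) and HRA (outer) — the zones' observed cork-spot risk increases
outward. The thirds are a package choice: the anatomy defines the zones
qualitatively, not numerically, and the fractions are exposed as a
parameter.

A healthy fruit core is denser (brighter) than the flesh and is extracted
by thresholding at the valley between the two brightest modes of the
histogram restricted to the central third of the fruit's bounding box
(modes below the dark/bright Otsu split are pore modes, not tissue
structures, and are excluded), keeping the component containing the fruit
centroid, and closing with a 2-voxel ball. When no second bright mode
exists — the disordered-fruit presentation — the condition is reported as a
classed error and the pipeline proceeds with a **fallback core**: a central
ellipsoid fitted to the fruit mask at 0.25 of its half-extents, flagged
`core_source = "fallback_ellipsoid"` in the report. Core failure is a
first-class outcome, not an abort.

Core shape metrics: solidity is voxel volume over the volume of the convex
hull of voxel centers (computed by an exact 3D hull on per-slice extreme
points), capped at 1 because digitization lets the voxel volume exceed the
center hull slightly for convex bodies. Sphericity is
$\pi^{1/3}(6V)^{2/3}/A$ with surface area $A$ from an orientation-weighted
exposed-face estimator: each exposed face contributes $h^2\,|n|_2/|n|_1$
with the normal $n$ taken from the gradient of a box-smoothed mask. The
weighting is exact for planar interfaces of any orientation; a calibration
factor of 1.01, fixed by measuring digitized balls of radii 6–30 voxels,
keeps the sphericity of balls at or below 1.

## The phantom generator

`generate_phantom()` emulates the study conditions, not scanner physics:

* a fruit-shaped ellipsoid (or a full-grid slab for flesh pieces) of bright
  tissue in dark air;
* spherical pore objects with fixed or lognormal diameters, placed at
  axially weighted random positions until a porosity (or count-density)
  target is met to within half of one object's contribution;
* an optional brighter core ellipsoid;
* independent Gaussian noise (default sd 8 on tissue 160 / pore 30), which
  leaves a deep histogram valley as in real fruit scans;
* exact ground truth: phase map, 26-labeled pore table, true porosity, and
  for tube phantoms the analytic centerline with radii.

Placement details that matter for validity: objects stay at least two
voxels clear of the fruit surface (a pore tangent to the surface would
connect to the outside air and silently leave both the mask and the pore
phase); with `allow_overlap = FALSE` objects keep a 1.8-voxel clearance —
more than one voxel diagonal — so ground-truth pore-table rows remain
one-to-one with 26-connected components. The U-shaped axial profile
$w(z) = 1 + 1.5\,(2u-1)^2$ places roughly 1.7× more pore volume in the end
quartiles than the middle half, reproducing the elevated porosity at both
fruit ends seen in disordered fruit. Everything is drawn from one
seeded RNG stream: the same spec and seed give bit-identical output, and
the caller's RNG state is restored.

**Presets** fix the study conditions as documented constants:

| preset | geometry | voxel | target | diameters |
|---|---|---|---|---|
| `healthy_whole` | ellipsoid + core (+40) | 79.4 µm | porosity 3.52% | lognormal(240 µm, 0.25) |
| `corkspot_whole` | ellipsoid, U-shaped axial, core offset 0 | 79.4 µm | porosity 9.37% | lognormal(260 µm, 0.30) |
| `hra_corkspot` | slab | 79.4 µm | porosity 20% | lognormal(300 µm, 0.30) |
| `mra_corkspot` | slab | 79.4 µm | porosity 5% | lognormal(260 µm, 0.30) |
| `healthy_mesocarp` | slab | 79.4 µm | porosity 1% | lognormal(240 µm, 0.25) |
| `healthy_flesh` | slab, non-overlap | 2 µm | porosity 3% | fixed 22 µm |
| `corkspot_flesh` | slab, non-overlap | 2 µm | porosity 5% | fixed 87 µm |

The porosity and diameter targets are the published levels for each tissue
class (whole-fruit 3.52% healthy vs 9.37% disordered; outer-mesocarp
15–30% → 20%; middle mesocarp ≈5%; healthy mesocarp below 1.5% → 1%; flesh
pore sizes 22 µm vs 87 µm). Flesh porosity targets are not published; 3%
and 5% were chosen once as the healthy-whole and middle-mesocarp levels of
the sampled tissue and are not tuned. Whole-fruit presets run on a 256³
grid — at the 79.4 µm scanner voxel this is a reduced-scale fruit
(≈20 mm), which preserves every per-voxel property (porosity, size
classes, histogram shape) at desk scale; the slab presets use 160×96×64,
flesh presets 384³ (a 0.77 mm piece at 2 µm; the published 0.5 µm at full
extent is not desk-scale). Lognormal diameter draws are clamped below at
one voxel radius.

**What phantoms do not emulate:** beam hardening, ring artifacts, partial-
volume blur at phase boundaries, anisotropic noise, non-spherical pore
shapes in the volumetric presets, and cell-wall-scale texture. Passing
tests therefore demonstrate that the *measurement chain* is correct and
unbiased under the stated intensity model — not that segmentation of a
particular scanner's data is artifact-free. The one deliberately hard
feature, pore coalescence, is present: overlap-allowed presets merge
objects exactly as real pores merge, and labeled counts are then counts of
connected voids, not of placed objects.

## Numerical choices and degenerate inputs

* Histograms: 256 unit bins (8-bit) or 1024 bins (16-bit); valley ties take
  the lowest bin; the smoothed moving average uses partial windows at the
  range ends so every bin is defined.
* Connected components and the distance transform are exact (validated
  against brute-force oracles in the test suite); distances are
  center-to-center, so a single pore voxel has distance one voxel.
* Thinning deletes sequentially within each directional subiteration with
  re-checking, so topology preservation is unconditional, at the cost of a
  deterministic but direction-ordered voxel selection; skeleton statistics
  are rotation-invariant to within a voxel step.
* Empty inputs: an empty histogram, empty mask, empty region or empty core
  raise errors; an empty pore phase yields an empty skeleton, an empty
  graph and all-zero network statistics rather than errors.
* Non-overlap placement beyond the random-sequential-adsorption jamming
  density of the clearance-inflated exclusion spheres cannot terminate;
  the generator stops after 10× the expected number of attempts and names
  the constraint.
* The Welch test degenerates when both samples are identical constants;
  `compare_groups()` returns $t = 0$, $p = 1$ for exactly identical
  samples instead of dividing by zero.

## Problem sizes used by the tests and acceptance script

Unit tests run on 15³–96³ fixtures (seconds). The acceptance checks run the
full presets: five seeds of each whole-fruit preset at 256³ and one flesh
phantom of each class at 384³; the complete test suite finishes in a few
minutes on one CPU, and `scripts/acceptance.R` in about two. These sizes
are the package's chosen study conditions, balancing statistical stability
(thousands of pores per phantom) against desk-scale runtimes.

## Known limitations

* The valley threshold assumes a genuinely bimodal masked histogram; heavy
  partial-volume mixing between phases would bias the valley position. The
  Otsu fallback is reported, not silent.
* Network extraction is skeleton-based. Maximal-ball or watershed
  pore-network partitions of the full voxel phase resolve wide, short
  throats better; the skeleton route was chosen because it matches the
  filar-centerline methodology being reproduced.
* Pore-body radii come from a single distance-map value, so strongly
  non-spherical bodies are summarized by their largest inscribed sphere.
* `extract_core()` assumes the central region contains pore voxels when it
  classifies dark modes; a perfectly pore-free center with a bright core
  would be mis-flagged as not separable (the fallback core then still
  yields a usable partition).
* Anisotropic voxels, DICOM input and projection-domain processing are out
  of scope; volumes must be reconstructed, isotropic grids.
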