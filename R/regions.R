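# Mesocarp risk-zone partitioning and fruit-core analysis. The mesocarp is
# split into LRA / MRA / HRA (inner, middle and outer zones, ordered by
# their observed cork-spot risk) by normalized depth between the core
# surface and the fruit skin. The core of a healthy fruit is brighter than
# the flesh and separable by grayscale; a disordered core with flesh-like
# texture is reported as "not separable" and a geometric fallback is used.

#' Extract the fruit core by grayscale
#'
#' Within the central third of the fruit's bounding box the histogram of a
#' fruit with an intact core is bimodal in its bright range (flesh mode and
#' brighter core mode); the threshold sits at the valley between the two
#' brightest modes. The component containing the fruit centroid is kept and
#' closed morphologically (radius 2 voxels). When no second bright mode
#' exists the core is not separable by grayscale and a classed error
#' (`fruitpore_core_error`) is raised; see [fallback_core()].
#'
#' @param vol a [voxel_volume()].
#' @param fruit_mask logical fruit mask.
#' @param smoothing_window histogram smoothing window (bins).
#' @param min_peak_frac a bright mode must reach this fraction of the
#'   tallest smoothed bin to count (guards against noise maxima).
#' @return Logical core mask.
#' @export
extract_core <- function(vol, fruit_mask, smoothing_window = 9L,
                         min_peak_frac = 0.05) {
  stopifnot(is_voxel_volume(vol))
  dims <- dim(vol$intensities)
  bb <- mask_bbox(fruit_mask)
  third <- function(lo, hi) {
    w <- hi - lo + 1L
    c(lo + floor(w / 3), hi - floor(w / 3))
  }
  xr <- third(bb[1L, 1L], bb[1L, 2L])
  yr <- third(bb[2L, 1L], bb[2L, 2L])
  zr <- third(bb[3L, 1L], bb[3L, 2L])
  box <- array(FALSE, dims)
  box[xr[1L]:xr[2L], yr[1L]:yr[2L], zr[1L]:zr[2L]] <- TRUE
  sel <- box & fruit_mask

  h <- compute_histogram(vol, sel)
  s <- smooth_counts(h$counts, as.integer(smoothing_window))
  peaks <- local_maxima(s)
  peaks <- peaks[s[peaks] >= min_peak_frac * max(s)]
  # the pore mode is not a tissue structure: when a dark mode exists below
  # the Otsu split of the central histogram, only modes above the split can
  # be the flesh and core modes
  t0 <- otsu_threshold(h)
  if (any(h$mids[peaks] < t0)) peaks <- peaks[h$mids[peaks] > t0]
  if (length(peaks) < 2L)
    core_error("core not separable by grayscale: central histogram has fewer than two bright modes")
  bright2 <- sort(peaks, decreasing = TRUE)[1:2]  # the two brightest modes
  lo <- min(bright2); hi <- max(bright2)
  if (hi - lo < 2L)
    core_error("core not separable by grayscale: bright modes are adjacent")
  between <- (lo + 1L):(hi - 1L)
  valley <- between[which.min(s[between])]
  T_core <- h$mids[valley]

  core0 <- sel & vol$intensities > T_core
  if (!any(core0))
    core_error("core not separable by grayscale: no voxels above the core threshold")
  lab <- label_components_cpp(core0, dims, 26L)
  cen <- round(colMeans(arrayInd(which(fruit_mask), dims)))
  cen_lab <- lab$labels[cen[1L], cen[2L], cen[3L]]
  if (cen_lab == 0L) {
    sizes <- tabulate(lab$labels[lab$labels > 0L], lab$n)
    cen_lab <- which.max(sizes)
  }
  core <- lab$labels == cen_lab
  dim(core) <- dims
  morph_close(core, 2) & fruit_mask
}

core_error <- function(msg) {
  stop(structure(class = c("fruitpore_core_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

mask_bbox <- function(mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  co <- arrayInd(which(mask), dim(mask))
  rbind(range(co[, 1L]), range(co[, 2L]), range(co[, 3L]))
}

# morphological closing (dilation then erosion) with a Euclidean ball,
# radius in voxels, via the distance transform
morph_close <- function(mask, radius) {
  dims <- dim(mask)
  dil <- mask | (edt_sq_cpp(!mask, dims) <= radius^2)
  dim(dil) <- dims
  ero <- dil & (edt_sq_cpp(dil, dims) > radius^2)
  dim(ero) <- dims
  ero
}

#' Geometric fallback core
#'
#' When the core cannot be separated by grayscale (the disordered-fruit
#' case), the analysis proceeds with a central ellipsoid fitted to the
#' fruit mask, each semi-axis 0.25 of the fruit's half-extent. Reported as
#' a fallback in the run report, never silently.
#'
#' @param fruit_mask logical fruit mask.
#' @param scale per-axis scale factor relative to the fruit half-extents.
#' @return Logical core mask.
#' @export
fallback_core <- function(fruit_mask, scale = 0.25) {
  bb <- mask_bbox(fruit_mask)
  center <- (bb[, 1L] + bb[, 2L]) / 2 - 1  # 0-based voxel coords
  semi <- pmax((bb[, 2L] - bb[, 1L]) / 2 * scale, 1)
  ellipsoid_mask(dim(fruit_mask), center, semi) & fruit_mask
}

#' Partition the mesocarp into LRA / MRA / HRA depth zones
#'
#' For each mesocarp voxel the normalized depth
#' `u = d_core / (d_core + d_skin)` (distance to the core surface over the
#' summed distances to core and skin) is 0 at the core and 1 at the skin.
#' Zone boundaries default to equal thirds: `u < 1/3` LRA (inner mesocarp),
#' `u < 2/3` MRA, else HRA (outer mesocarp, where cork spot develops).
#'
#' @param fruit_mask logical fruit mask.
#' @param core_mask logical core mask, strictly inside the fruit.
#' @param fractions two numbers `0 < f1 < f2 < 1` splitting the depth.
#' @return A `region_partition`: list with `labels` (0 background, 1 core,
#'   2 LRA, 3 MRA, 4 HRA) and `fractions`.
#' @export
partition_mesocarp <- function(fruit_mask, core_mask, fractions = c(1/3, 2/3)) {
  if (length(fractions) != 2L || !(0 < fractions[1L]) ||
      !(fractions[1L] < fractions[2L]) || !(fractions[2L] < 1))
    stop("fractions must satisfy 0 < f1 < f2 < 1", call. = FALSE)
  if (!any(core_mask)) stop("empty core mask", call. = FALSE)
  if (any(core_mask & !fruit_mask))
    stop("core must lie strictly inside the fruit", call. = FALSE)
  if (!any(fruit_mask & !core_mask))
    stop("fruit has no mesocarp outside the core", call. = FALSE)
  dims <- dim(fruit_mask)
  d_core <- sqrt(edt_sq_cpp(!core_mask, dims))   # distance to core
  d_skin <- sqrt(edt_sq_cpp(fruit_mask, dims))   # distance to outside
  meso <- fruit_mask & !core_mask
  u <- d_core[meso] / pmax(d_core[meso] + d_skin[meso], 1e-12)
  lab <- array(0L, dims)
  lab[core_mask] <- 1L
  zone <- ifelse(u < fractions[1L], 2L, ifelse(u < fractions[2L], 3L, 4L))
  lab[meso] <- zone
  structure(list(labels = lab, fractions = fractions),
            class = "region_partition")
}

#' Region masks of a partition
#'
#' @param part a `region_partition`.
#' @return Named list of logical masks: core, LRA, MRA, HRA.
#' @export
region_masks <- function(part) {
  stopifnot(inherits(part, "region_partition"))
  list(core = part$labels == 1L, LRA = part$labels == 2L,
       MRA = part$labels == 3L, HRA = part$labels == 4L)
}

#' Core shape metrics
#'
#' Volume, solidity and sphericity of a core mask. Solidity is the voxel
#' volume over the volume of the convex hull of voxel centers, capped at 1
#' (digitization lets the voxel volume exceed the center hull slightly for
#' convex bodies). Sphericity is `pi^(1/3) (6V)^(2/3) / A` with the surface
#' area `A` from an orientation-weighted exposed-face estimator (exact on
#' planar interfaces) calibrated so digitized balls stay at or below 1.
#'
#' @param core_mask logical core mask (non-empty).
#' @param voxel_size_um voxel size in micrometers.
#' @return `list(volume_mm3, solidity, sphericity, surface_area_um2)`.
#' @export
core_shape_metrics <- function(core_mask, voxel_size_um) {
  if (!any(core_mask)) stop("empty core mask", call. = FALSE)
  dims <- dim(core_mask)
  nvox <- sum(core_mask)
  V <- nvox * voxel_size_um^3

  # hull candidates: per-slice 2D convex hull extreme points (a 3D hull
  # vertex must be a 2D hull vertex of its own slice)
  pts <- NULL
  for (z in seq_len(dims[3L])) {
    sl <- which(core_mask[, , z], arr.ind = TRUE)
    if (nrow(sl) == 0L) next
    if (nrow(sl) > 2L) sl <- sl[chull(sl[, 1L], sl[, 2L]), , drop = FALSE]
    pts <- rbind(pts, cbind(sl, z))
  }
  Vh <- convex_hull_volume_cpp(pts * voxel_size_um) # centers: offset cancels
  solidity <- if (Vh > 0) min(1, V / Vh) else 1

  A <- surface_area_cpp(core_mask, dims, voxel_size_um) * SURFACE_CAL
  sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  list(volume_mm3 = V / 1e9, solidity = solidity, sphericity = sphericity,
       surface_area_um2 = A)
}

# Surface-area calibration: the face estimator with smoothed-gradient
# normals is exact on planes but biased slightly low on curved digitized
# surfaces; the factor keeps digitized balls (radius >= ~6 voxels) at
# sphericity <= 1.
SURFACE_CAL <- 1.01
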