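# Individual-pore morphometry: labeling, equivalent-sphere diameters,
# porosity, axial porosity profiles, size histograms and number density.

#' Label individual pores
#'
#' Connected components of the pore phase. The default 26-connectivity
#' joins voxels sharing a face, an edge or a corner; 6-connectivity
#' (faces only) is retained for sensitivity checks. Ids are dense 1..K in
#' ascending order of each pore's first voxel in array scan order.
#'
#' @param phase a `phase_map` (from [segment_phases()]) or logical pore array.
#' @param connectivity 26 (default) or 6.
#' @param min_voxels drop pores smaller than this many voxels (default 1,
#'   i.e. no filtering; scanner-noise handling is left to the caller).
#' @return A `pore_label_map`: list with `labels` (int array, 0 = not pore),
#'   `n`, `connectivity`, `voxel_size_um`.
#' @export
label_pores <- function(phase, connectivity = 26L, min_voxels = 1L) {
  if (is_phase_map(phase)) {
    pore <- phase$phase == 2L
    vx <- phase$voxel_size_um
  } else {
    pore <- phase
    vx <- attr(phase, "voxel_size_um")
    if (is.null(vx)) vx <- 1
  }
  lab <- label_components_cpp(pore, dim(pore), as.integer(connectivity))
  labels <- lab$labels
  n <- lab$n
  if (min_voxels > 1L && n > 0L) {
    sizes <- tabulate(labels[labels > 0L], n)
    keep <- sizes >= min_voxels
    remap <- integer(n)
    remap[keep] <- seq_len(sum(keep))
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    n <- sum(keep)
    dim(labels) <- dim(pore)
  }
  structure(list(labels = labels, n = n,
                 connectivity = as.integer(connectivity),
                 voxel_size_um = vx),
            class = "pore_label_map")
}

#' Per-pore morphometry table
#'
#' One row per labeled pore: voxel count, physical volume, equivalent
#' diameter (the diameter of the sphere with the same volume,
#' `d_eq = (6 V / pi)^(1/3)`), and centroid of voxel centers in physical
#' micrometers (voxel-center convention: position = (index + 0.5) * voxel).
#'
#' @param labels a `pore_label_map` from [label_pores()].
#' @return A data.frame with columns `id`, `voxel_count`, `volume_um3`,
#'   `d_eq_um`, `x_um`, `y_um`, `z_um`.
#' @export
build_pore_table <- function(labels) {
  stopifnot(inherits(labels, "pore_label_map"))
  vx <- labels$voxel_size_um
  K <- labels$n
  if (K == 0L)
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), d_eq_um = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0)))
  idx <- which(labels$labels > 0L)
  ids <- labels$labels[idx]
  counts <- tabulate(ids, K)
  co <- arrayInd(idx, dim(labels$labels))
  cx <- rowsum(co[, 1L] - 0.5, ids)[, 1L] / counts  # (index-1) + 0.5
  cy <- rowsum(co[, 2L] - 0.5, ids)[, 1L] / counts
  cz <- rowsum(co[, 3L] - 0.5, ids)[, 1L] / counts
  vol <- counts * vx^3
  data.frame(id = seq_len(K), voxel_count = counts, volume_um3 = vol,
             d_eq_um = (6 * vol / pi)^(1 / 3),
             x_um = cx * vx, y_um = cy * vx, z_um = cz * vx)
}

#' Porosity of a region
#'
#' Pore voxels divided by all voxels of the region, in percent.
#'
#' @param phase a `phase_map`.
#' @param region_mask logical array (subset of the fruit mask); default: the
#'   whole fruit (phase != background).
#' @return Porosity in percent.
#' @export
porosity <- function(phase, region_mask = NULL) {
  stopifnot(is_phase_map(phase))
  if (is.null(region_mask)) region_mask <- phase$phase != 0L
  ntot <- sum(region_mask)
  if (ntot == 0) stop("empty region", call. = FALSE)
  100 * sum(phase$phase[region_mask] == 2L) / ntot
}

#' Axial porosity profile
#'
#' Per-slice porosity within each slice's fruit cross-section, running
#' calyx end (slice 1) to stem end (last slice). Slices with an empty
#' fruit cross-section are flagged (`NA` porosity), not zero-filled.
#'
#' @param phase a `phase_map`.
#' @return A data.frame with `slice`, `porosity_percent`, `mask_voxels`,
#'   `empty`.
#' @export
porosity_profile <- function(phase) {
  stopifnot(is_phase_map(phase))
  d <- dim(phase$phase)
  m <- matrix(phase$phase, nrow = d[1L] * d[2L], ncol = d[3L])
  mask_n <- colSums(m != 0L)
  pore_n <- colSums(m == 2L)
  data.frame(slice = seq_len(d[3L]),
             porosity_percent = ifelse(mask_n > 0L, 100 * pore_n / mask_n, NA_real_),
             mask_voxels = mask_n,
             empty = mask_n == 0L)
}

#' Pore-size histogram in fixed classes
#'
#' Equivalent diameters are assigned to the nearest class center
#' (100, 200, ..., `max_um` micrometers by default); diameters at or beyond
#' the top class fall into the top class. This reproduces the labeled
#' 100-um classes of whole-fruit pore-size histograms.
#'
#' @param table a pore table from [build_pore_table()].
#' @param class_width_um class width (default 100).
#' @param max_um top class center (default 3000).
#' @return A data.frame with `class_um` (center) and `count`.
#' @export
pore_size_histogram <- function(table, class_width_um = 100, max_um = 3000) {
  ncls <- round(max_um / class_width_um)
  cls <- pmin(pmax(round(table$d_eq_um / class_width_um), 1L), ncls)
  data.frame(class_um = seq_len(ncls) * class_width_um,
             count = tabulate(cls, ncls))
}

#' Pore number density
#'
#' @param table a pore table from [build_pore_table()].
#' @param region_volume_mm3 volume of the analyzed region in cubic
#'   millimeters (> 0).
#' @return Pores per cubic millimeter.
#' @export
pore_number_density <- function(table, region_volume_mm3) {
  if (!is.numeric(region_volume_mm3) || region_volume_mm3 <= 0)
    stop("region volume must be positive", call. = FALSE)
  nrow(table) / region_volume_mm3
}
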