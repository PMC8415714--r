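# Synthetic fruit phantoms with exact pore-phase ground truth.
#
# A phantom is a fruit-shaped (ellipsoidal) or slab-shaped tissue matrix at
# a given voxel size, into which spherical pore objects are placed until a
# porosity or count-density target is met, rendered as an 8-bit grayscale
# volume: bright tissue, dark pores (pores have lower X-ray attenuation),
# optional brighter core, independent Gaussian noise. The emitted ground
# truth (phase map, pore table, true porosity, and for tube phantoms the
# exact centerline) is what every pipeline stage is validated against.

#' Specify a synthetic fruit phantom
#'
#' @param grid_shape integer vector of 3 positive dimensions.
#' @param voxel_size_um isotropic voxel size in micrometers.
#' @param fruit_shape `list(type = "ellipsoid", semi_axes_um = c(a, b, c))`
#'   for a whole fruit in air, or `list(type = "slab")` for a flesh piece
#'   filling the grid.
#' @param core optional `list(semi_axes_um =, center_offset_um = c(0,0,0),
#'   intensity_offset =)` describing a denser (brighter) central core.
#' @param pore_model list with exactly one of `target_porosity_percent`
#'   (in `[0, 50)`) or `count_density_per_mm3`, plus `diameter`: either
#'   `list(kind = "lognormal", median_um =, sigma_log =)` or
#'   `list(kind = "fixed", d_um =)`.
#' @param axial_profile `"constant"`, `"u_shaped"` (pore placement weighted
#'   toward the calyx and stem ends), or `"linear"`.
#' @param intensity_model list with `tissue_mean`, `pore_mean`, `sd`
#'   (8-bit units); `pore_mean < tissue_mean` is required. The surrounding
#'   air is rendered at `pore_mean` (air attenuates like pores).
#' @param allow_overlap if `FALSE`, placed objects keep a 1.8-voxel tissue
#'   clearance (more than one voxel diagonal, so corner adjacency is ruled
#'   out) and ground-truth pore-table rows stay one-to-one with
#'   26-connected components.
#' @param seed mandatory integer seed; identical spec + seed gives a
#'   bit-identical phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size_um,
                         fruit_shape = list(type = "slab"),
                         core = NULL,
                         pore_model = list(target_porosity_percent = 5,
                                           diameter = list(kind = "fixed", d_um = 4 * voxel_size_um)),
                         axial_profile = c("constant", "u_shaped", "linear"),
                         intensity_model = list(tissue_mean = 160, pore_mean = 30, sd = 8),
                         allow_overlap = TRUE,
                         seed) {
  axial_profile <- match.arg(axial_profile)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            voxel_size_um > 0)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory for phantom generation", call. = FALSE)
  has_por <- !is.null(pore_model$target_porosity_percent)
  has_den <- !is.null(pore_model$count_density_per_mm3)
  if (has_por == has_den)
    stop("exactly one of target_porosity_percent / count_density_per_mm3 ",
         "must be set", call. = FALSE)
  if (has_por) {
    p <- pore_model$target_porosity_percent
    if (p < 0 || p >= 50)
      stop("target_porosity_percent must lie in [0, 50)", call. = FALSE)
  }
  im <- intensity_model
  if (!(im$pore_mean < im$tissue_mean))
    stop("pore_mean must be below tissue_mean (pores are dark)", call. = FALSE)
  dk <- pore_model$diameter$kind
  if (!dk %in% c("fixed", "lognormal"))
    stop("diameter$kind must be 'fixed' or 'lognormal'", call. = FALSE)
  d_ref <- if (dk == "fixed") pore_model$diameter$d_um
           else pore_model$diameter$median_um
  if (d_ref < voxel_size_um)
    stop("pore diameters must be at least one voxel", call. = FALSE)
  if (identical(fruit_shape$type, "ellipsoid") &&
      any(fruit_shape$semi_axes_um < voxel_size_um))
    stop("ellipsoid semi-axes must be at least one voxel", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_um = voxel_size_um,
                 fruit_shape = fruit_shape, core = core,
                 pore_model = pore_model, axial_profile = axial_profile,
                 intensity_model = im, allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Named presets. Whole-fruit presets emulate the study conditions at the
# scanner voxel size of 79.4 um on a desk-scale grid (a reduced-scale fruit);
# porosity targets are the published whole-fruit values (healthy 3.52 %,
# cork spotted 9.37 %), zone presets the published mesocarp levels
# (HRA 15-30 % -> 20 %, MRA ~5 %, healthy mesocarp < 1.5 % -> 1 %). Flesh
# presets emulate the high-resolution flesh pieces: monodisperse spheres at
# the published mean pore sizes (22 um healthy, 87 um cork spotted) at a
# 2 um voxel.
preset_table <- function() list(
  healthy_whole = list(kind = "whole", porosity = 3.52,
                       diameter = list(kind = "lognormal", median_um = 240,
                                       sigma_log = 0.25),
                       profile = "constant", core_offset = 40),
  corkspot_whole = list(kind = "whole", porosity = 9.37,
                        diameter = list(kind = "lognormal", median_um = 260,
                                        sigma_log = 0.30),
                        profile = "u_shaped", core_offset = 0),
  hra_corkspot = list(kind = "slab", porosity = 20,
                      diameter = list(kind = "lognormal", median_um = 300,
                                      sigma_log = 0.30)),
  mra_corkspot = list(kind = "slab", porosity = 5,
                      diameter = list(kind = "lognormal", median_um = 260,
                                      sigma_log = 0.30)),
  healthy_mesocarp = list(kind = "slab", porosity = 1,
                          diameter = list(kind = "lognormal", median_um = 240,
                                          sigma_log = 0.25)),
  healthy_flesh = list(kind = "flesh", porosity = 3,
                       diameter = list(kind = "fixed", d_um = 22)),
  corkspot_flesh = list(kind = "flesh", porosity = 5,
                        diameter = list(kind = "fixed", d_um = 87)))

#' Phantom preset specifications
#'
#' Documented constants reproducing the study conditions: `healthy_whole`
#' (porosity 3.52 %), `corkspot_whole` (9.37 %, U-shaped axial pore
#' placement), `hra_corkspot` (20 %), `mra_corkspot` (5 %),
#' `healthy_mesocarp` (1 %), `healthy_flesh` (monodisperse 22 um spheres at
#' 2 um voxels), `corkspot_flesh` (87 um spheres). Whole-fruit and mesocarp
#' presets use the 79.4 um scanner voxel; flesh presets a 2 um voxel.
#'
#' @param name preset name (see above).
#' @param seed integer seed for the phantom.
#' @param grid_shape optional override of the default grid (whole fruit
#'   256^3, flesh 384^3, mesocarp slabs 160 x 96 x 64); smaller grids give
#'   proportionally scaled fruit.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name, seed, grid_shape = NULL) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  p <- tab[[name]]
  if (p$kind == "whole") {
    if (is.null(grid_shape)) grid_shape <- c(256L, 256L, 256L)
    vx <- 79.4
    semi <- c(0.39, 0.39, 0.45) * grid_shape * vx
    core <- list(semi_axes_um = 0.25 * semi, center_offset_um = c(0, 0, 0),
                 intensity_offset = p$core_offset)
    phantom_spec(grid_shape, vx,
                 fruit_shape = list(type = "ellipsoid", semi_axes_um = semi),
                 core = core,
                 pore_model = list(target_porosity_percent = p$porosity,
                                   diameter = p$diameter),
                 axial_profile = p$profile,
                 allow_overlap = TRUE, seed = seed)
  } else if (p$kind == "slab") {
    if (is.null(grid_shape)) grid_shape <- c(160L, 96L, 64L)
    phantom_spec(grid_shape, 79.4,
                 fruit_shape = list(type = "slab"),
                 pore_model = list(target_porosity_percent = p$porosity,
                                   diameter = p$diameter),
                 axial_profile = "constant",
                 allow_overlap = TRUE, seed = seed)
  } else { # flesh
    if (is.null(grid_shape)) grid_shape <- c(384L, 384L, 384L)
    phantom_spec(grid_shape, 2,
                 fruit_shape = list(type = "slab"),
                 pore_model = list(target_porosity_percent = p$porosity,
                                   diameter = p$diameter),
                 axial_profile = "constant",
                 allow_overlap = FALSE, seed = seed)
  }
}

# Ellipsoid occupancy by the voxel-center rule; semi-axes in voxels,
# center in 0-based voxel coordinates. Built from separable squared terms.
ellipsoid_mask <- function(grid_shape, center, semi) {
  xs <- ((seq_len(grid_shape[1L]) - 1 - center[1L]) / semi[1L])^2
  ys <- ((seq_len(grid_shape[2L]) - 1 - center[2L]) / semi[2L])^2
  zs <- ((seq_len(grid_shape[3L]) - 1 - center[3L]) / semi[3L])^2
  m <- outer(outer(xs, ys, `+`), zs, `+`) <= 1
  m
}

axial_weight <- function(profile, u) {
  switch(profile,
         constant = rep(1, length(u)),
         u_shaped = 1 + 1.5 * (2 * u - 1)^2,
         linear = 0.5 + u)
}

#' Generate a synthetic fruit phantom
#'
#' Places spherical pore objects at axially weighted random positions inside
#' the fruit, with diameters drawn from `spec`'s diameter distribution, until the
#' porosity (or object-count) target is met to within half of one object's
#' contribution, then renders phase mean intensities plus independent
#' Gaussian noise clamped to the 8-bit range. Placement that cannot reach
#' the target within 10x the expected number of attempts (e.g. non-overlap
#' exhaustion) fails with an informative error. Identical spec and seed give
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = voxel_volume, truth = list(phase_map, core_mask,
#'   pore_table, placed, true_porosity_percent, fruit_voxels, spec))`.
#'   `phase_map` codes 0 = background air, 1 = tissue, 2 = pore.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  gs <- spec$grid_shape
  vx <- spec$voxel_size_um
  n <- prod(gs)
  center <- (gs - 1) / 2

  if (identical(spec$fruit_shape$type, "ellipsoid")) {
    semi_vox <- spec$fruit_shape$semi_axes_um / vx
    region <- ellipsoid_mask(gs, center, semi_vox)
  } else {
    semi_vox <- NULL
    region <- array(TRUE, dim = gs)
  }
  region_n <- sum(region)

  core_mask <- NULL
  if (!is.null(spec$core)) {
    core_center <- center + spec$core$center_offset_um / vx
    core_mask <- ellipsoid_mask(gs, core_center, spec$core$semi_axes_um / vx)
    core_mask <- core_mask & region
  }

  # z range available for placement (fruit extent along the axis)
  if (!is.null(semi_vox)) {
    z_lo <- max(0, center[3L] - semi_vox[3L])
    z_hi <- min(gs[3L] - 1, center[3L] + semi_vox[3L])
  } else {
    z_lo <- 0; z_hi <- gs[3L] - 1
  }

  pm <- spec$pore_model
  draw_d_um <- function(m) {
    if (pm$diameter$kind == "fixed") rep(pm$diameter$d_um, m)
    else rlnorm(m, log(pm$diameter$median_um), pm$diameter$sigma_log)
  }
  mean_obj_vox <- {
    if (pm$diameter$kind == "fixed") {
      r <- max(pm$diameter$d_um / 2 / vx, 1)
      4 / 3 * pi * r^3
    } else {
      dv <- pmax(pm$diameter$median_um / vx, 2) # rough; exact value immaterial
      4 / 3 * pi * (dv / 2)^3 * exp(4.5 * pm$diameter$sigma_log^2)
    }
  }

  if (!is.null(pm$target_porosity_percent)) {
    target_vox <- pm$target_porosity_percent / 100 * region_n
    target_obj <- 0L
    n_expected <- max(1, ceiling(target_vox / mean_obj_vox))
  } else {
    region_mm3 <- region_n * (vx / 1000)^3
    target_obj <- as.integer(round(pm$count_density_per_mm3 * region_mm3))
    target_vox <- 0
    n_expected <- max(1L, target_obj)
  }

  n_cand <- as.integer(min(10 * n_expected + 50, 5e7))
  d_um <- draw_d_um(n_cand)
  r_vox <- pmax(d_um / 2 / vx, 1)
  # candidate centers: uniform over the fruit bounding box, kept when the
  # object fits inside the (per-radius eroded) fruit, thinned by the axial
  # placement weight
  if (!is.null(semi_vox)) {
    cx <- runif(n_cand, center[1L] - semi_vox[1L], center[1L] + semi_vox[1L])
    cy <- runif(n_cand, center[2L] - semi_vox[2L], center[2L] + semi_vox[2L])
    cz <- runif(n_cand, z_lo, z_hi)
    # keep a >= 2-voxel tissue shell above every pore: a pore tangent to the
    # fruit surface would otherwise connect to the outside air and escape
    # both the hole-filling mask and the enclosed pore space
    er <- pmax(cbind(semi_vox[1L] - r_vox - 2, semi_vox[2L] - r_vox - 2,
                     semi_vox[3L] - r_vox - 2), 1e-9)
    inside <- ((cx - center[1L]) / er[, 1L])^2 +
      ((cy - center[2L]) / er[, 2L])^2 +
      ((cz - center[3L]) / er[, 3L])^2 <= 1
  } else {
    # out-of-bound candidates (object would touch the border) are rejected
    # by the placement kernel and count as attempts
    cx <- runif(n_cand, 0, gs[1L] - 1)
    cy <- runif(n_cand, 0, gs[2L] - 1)
    cz <- runif(n_cand, 0, gs[3L] - 1)
    inside <- rep(TRUE, n_cand)
  }
  u <- (cz - z_lo) / max(z_hi - z_lo, 1e-9)
  w <- axial_weight(spec$axial_profile, u)
  keep <- inside & runif(n_cand) <= w / max(w)

  no_pores <- (!is.null(pm$target_porosity_percent) &&
                 pm$target_porosity_percent == 0) ||
    (is.null(pm$target_porosity_percent) && target_obj == 0L)
  if (no_pores) {
    placed <- list(labels = array(0L, dim = gs), placed = integer(0),
                   voxel_count = integer(0), total_voxels = 0,
                   target_reached = TRUE)
  } else {
    placed <- place_spheres_cpp(gs, region, cx[keep], cy[keep], cz[keep],
                                r_vox[keep], spec$allow_overlap,
                                clearance = 1.8,
                                target_voxels = target_vox,
                                target_objects = target_obj)
  }
  if (!isTRUE(placed$target_reached))
    stop("phantom generation failure: placement target not reached within ",
         "10x the expected number of attempts (constraint: ",
         if (spec$allow_overlap) "fruit interior" else "non-overlap", ")",
         call. = FALSE)
  pore_ids <- placed$labels
  pore <- pore_ids > 0L

  # render intensities
  im <- spec$intensity_model
  intens <- array(im$pore_mean, dim = gs)
  intens[region] <- im$tissue_mean
  if (!is.null(core_mask) && !is.null(spec$core$intensity_offset))
    intens[core_mask] <- im$tissue_mean + spec$core$intensity_offset
  intens[pore] <- im$pore_mean
  if (im$sd > 0) intens <- intens + rnorm(n, 0, im$sd)
  intens <- as.integer(floor(pmin(pmax(intens, 0), 255) + 0.5))
  dim(intens) <- gs

  phase <- array(0L, dim = gs)
  phase[region] <- 1L
  phase[pore] <- 2L

  vol <- voxel_volume(intens, vx, bit_depth = 8L,
                      provenance = sprintf("phantom seed %d", spec$seed))
  truth_phase <- new_phase_map(phase, vx)
  pore_table <- build_pore_table(label_pores(truth_phase, connectivity = 26L))
  kidx <- which(keep)[placed$placed]
  placed_tab <- data.frame(id = seq_along(kidx),
                           x_vox = cx[kidx], y_vox = cy[kidx], z_vox = cz[kidx],
                           radius_um = r_vox[kidx] * vx,
                           voxel_count = placed$voxel_count)
  truth <- list(phase_map = truth_phase,
                core_mask = core_mask,
                fruit_mask = region,
                pore_table = pore_table,
                placed = placed_tab,
                true_porosity_percent = 100 * sum(pore & region) / region_n,
                fruit_voxels = region_n,
                spec = spec)
  list(volume = vol, truth = truth)
}

#' Generate a tube phantom with exact centerline ground truth
#'
#' The pore phase is a union of capsules (cylinders with hemispherical
#' caps); the ground-truth skeleton is the given set of segments. Used to
#' validate skeletonization and network extraction against known topology,
#' lengths and radii.
#'
#' @param segments list of `list(start = c(x,y,z), end = c(x,y,z),
#'   radius = r)`, all in 0-based voxel units (multiply by `voxel_size_um`
#'   for physical positions).
#' @param grid_shape dimensions of the volume.
#' @param voxel_size_um voxel size (default 1, so voxel and micrometer
#'   coordinates coincide).
#' @param intensity_model as in [phantom_spec()]; default noise-free.
#' @return `list(volume, truth)` where truth holds the segment table, total
#'   centerline length, junction/endpoint coordinates and component count.
#' @export
generate_tube_phantom <- function(segments, grid_shape, voxel_size_um = 1,
                                  intensity_model = list(tissue_mean = 160,
                                                         pore_mean = 30, sd = 0)) {
  gs <- as.integer(grid_shape)
  stopifnot(length(gs) == 3L)
  pore <- array(FALSE, dim = gs)
  seg_tab <- data.frame(x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                        x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                        radius_vox = numeric(0), length_vox = numeric(0))
  for (s in segments) {
    a <- as.numeric(s$start); b <- as.numeric(s$end); r <- as.numeric(s$radius)
    len <- sqrt(sum((b - a)^2))
    if (len == 0) stop("zero-length segment", call. = FALSE)
    lo <- floor(pmin(a, b) - r); hi <- ceiling(pmax(a, b) + r)
    if (any(lo < 0) || any(hi > gs - 1))
      stop("segment (with radius) extends outside the grid", call. = FALSE)
    xr <- lo[1L]:hi[1L]; yr <- lo[2L]:hi[2L]; zr <- lo[3L]:hi[3L]
    g <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
    ab <- b - a
    t <- ((g[, 1L] - a[1L]) * ab[1L] + (g[, 2L] - a[2L]) * ab[2L] +
            (g[, 3L] - a[3L]) * ab[3L]) / sum(ab^2)
    t <- pmin(pmax(t, 0), 1)
    px <- a[1L] + t * ab[1L]; py <- a[2L] + t * ab[2L]; pz <- a[3L] + t * ab[3L]
    d2 <- (g[, 1L] - px)^2 + (g[, 2L] - py)^2 + (g[, 3L] - pz)^2
    sel <- g[d2 <= r^2, , drop = FALSE]
    if (nrow(sel) > 0L)
      pore[cbind(sel[, 1L] + 1L, sel[, 2L] + 1L, sel[, 3L] + 1L)] <- TRUE
    seg_tab <- rbind(seg_tab,
                     data.frame(x0 = a[1L], y0 = a[2L], z0 = a[3L],
                                x1 = b[1L], y1 = b[2L], z1 = b[3L],
                                radius_vox = r, length_vox = len))
  }

  im <- intensity_model
  intens <- array(im$tissue_mean, dim = gs)
  intens[pore] <- im$pore_mean
  if (im$sd > 0) intens <- intens + rnorm(prod(gs), 0, im$sd)
  intens <- as.integer(floor(pmin(pmax(intens, 0), 255) + 0.5))
  dim(intens) <- gs

  # endpoint/junction bookkeeping from shared segment endpoints
  pts <- rbind(as.matrix(seg_tab[, 1:3]), as.matrix(seg_tab[, 4:6]))
  key <- apply(round(pts, 6), 1L, paste, collapse = ",")
  use <- table(key)
  junctions <- unique(pts[key %in% names(use)[use >= 3L], , drop = FALSE])
  endpoints <- unique(pts[key %in% names(use)[use == 1L], , drop = FALSE])
  # connected components of the segment graph (segments sharing an endpoint)
  ns <- nrow(seg_tab)
  comp <- seq_len(ns)
  k1 <- key[seq_len(ns)]; k2 <- key[ns + seq_len(ns)]
  repeat {
    changed <- FALSE
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (comp[i] != comp[j] &&
          (k1[i] == k1[j] || k1[i] == k2[j] || k2[i] == k1[j] || k2[i] == k2[j])) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  phase <- array(1L, dim = gs)
  phase[pore] <- 2L
  truth <- list(phase_map = new_phase_map(phase, voxel_size_um),
                segments = seg_tab,
                total_length_vox = sum(seg_tab$length_vox),
                junctions = junctions,
                endpoints = endpoints,
                n_components = length(unique(comp)))
  vol <- voxel_volume(intens, voxel_size_um, bit_depth = 8L,
                      provenance = "tube phantom")
  list(volume = vol, truth = truth)
}
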