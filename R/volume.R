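#' Voxel volume container
#'
#' A `voxel_volume` wraps a 3D array of unsigned integer grayscale
#' intensities together with the physical voxel edge length and the axial
#' convention used throughout the package: slice index 1 is the calyx end of
#' the fruit, the last slice the stem end.
#'
#' @param intensities 3D array of non-negative integers (8- or 16-bit range).
#' @param voxel_size_um isotropic voxel edge length in micrometers (> 0).
#' @param bit_depth 8 or 16; inferred from the data range when `NULL`.
#' @param axis_convention character note on slice ordering; kept verbatim and
#'   propagated by all downstream stages.
#' @param provenance free-text metadata (source file, scan settings).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, voxel_size_um, bit_depth = NULL,
                         axis_convention = "slice 1 = calyx end, last slice = stem end",
                         provenance = character()) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array", call. = FALSE)
  if (any(dim(intensities) < 1L))
    stop("all three dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive scalar", call. = FALSE)
  storage.mode(intensities) <- "integer"
  rng <- range(intensities)
  if (is.na(rng[1L])) stop("intensities contain NA", call. = FALSE)
  if (rng[1L] < 0L) stop("intensities must be non-negative", call. = FALSE)
  if (is.null(bit_depth)) bit_depth <- if (rng[2L] <= 255L) 8L else 16L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  if (rng[2L] > 2^bit_depth - 1L)
    stop("intensities exceed the declared bit depth", call. = FALSE)
  structure(
    list(intensities = intensities,
         voxel_size_um = as.numeric(voxel_size_um),
         bit_depth = bit_depth,
         axis_convention = axis_convention,
         provenance = provenance),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %d-bit, voxel %.4g um\n",
              d[1L], d[2L], d[3L], x$bit_depth, x$voxel_size_um))
  cat(" axis: ", x$axis_convention, "\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$intensities)

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

#' Rescale a volume to 8 bits
#'
#' Linear windowing: intensity `v` maps to
#' `round(255 * (clamp(v, window) - window_min) / (window_max - window_min))`
#' with half-away-from-zero rounding, the convention under which the window
#' midpoint lands on 128. The default window is the observed intensity range
#' of the volume, which is parameter-free and preserves the histogram shape
#' that the valley-threshold detector relies on.
#'
#' @param vol a [voxel_volume()].
#' @param window_min,window_max window bounds on the input intensity scale;
#'   values outside are clamped. `window_min < window_max` is required.
#' @return An 8-bit `voxel_volume` with unchanged voxel size and metadata.
#' @export
convert_to_8bit <- function(vol, window_min = NULL, window_max = NULL) {
  stopifnot(is_voxel_volume(vol))
  v <- vol$intensities
  if (is.null(window_min)) window_min <- min(v)
  if (is.null(window_max)) window_max <- max(v)
  if (!(window_min < window_max))
    stop("degenerate window: window_min must be < window_max", call. = FALSE)
  x <- (pmin(pmax(as.numeric(v), window_min), window_max) - window_min) /
    (window_max - window_min) * 255
  # half-away-from-zero; x is non-negative here
  out <- as.integer(floor(x + 0.5))
  dim(out) <- dim(v)
  voxel_volume(out, vol$voxel_size_um, bit_depth = 8L,
               axis_convention = vol$axis_convention,
               provenance = c(vol$provenance,
                              sprintf("8-bit window [%g, %g]", window_min, window_max)))
}

#' Map a threshold through an 8-bit conversion window
#'
#' Companion to [convert_to_8bit()]: returns the threshold on the 8-bit scale
#' that corresponds to `threshold` on the original scale, so porosity
#' measured before and after conversion agrees.
#'
#' Because conversion rounds to integers, the exact image of a threshold is
#' the midpoint between the 8-bit values of the last intensity below it and
#' the first at/above it; using the raw linear image instead can flip voxels
#' whose rounded value crosses it. The window must be wide open (no clipping
#' across the threshold) and expanding enough that those two intensities stay
#' distinct at 8 bits, otherwise the conversion is not invertible there and
#' an error is raised.
#'
#' @param threshold threshold on the original intensity scale.
#' @param window_min,window_max the window used for the conversion.
#' @return Threshold on the 0-255 scale (possibly fractional).
#' @export
map_threshold_to_8bit <- function(threshold, window_min, window_max) {
  stopifnot(window_min < window_max)
  s <- function(v) 255 * (pmin(pmax(v, window_min), window_max) - window_min) /
    (window_max - window_min)
  r <- function(x) floor(x + 0.5)
  below <- ceiling(threshold) - 1  # last integer intensity classified as pore
  lo <- r(s(below))
  hi <- r(s(ceiling(threshold)))
  if (hi <= lo)
    stop("window compresses intensities around the threshold; ",
         "the mapped threshold is not well defined", call. = FALSE)
  (lo + hi) / 2
}
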