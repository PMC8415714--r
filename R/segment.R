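# Fruit/air masking, grayscale histograms, deep-valley global thresholding
# and tissue/pore phase segmentation. Surrounding air attenuates X-rays as
# little as the pores do, so the fruit must be masked before the pore/tissue
# histogram is built; the global threshold then sits in the deep valley
# between the dark (pore) and bright (tissue) modes.

new_phase_map <- function(phase, voxel_size_um, threshold = NA_real_) {
  structure(list(phase = phase, voxel_size_um = voxel_size_um,
                 threshold = threshold),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_map> %d x %d x %d (0 bg / 1 tissue / 2 pore), voxel %.4g um\n",
              d[1L], d[2L], d[3L], x$voxel_size_um))
  invisible(x)
}

is_phase_map <- function(x) inherits(x, "phase_map")

#' Mask the fruit against the surrounding air
#'
#' Otsu threshold on the full volume, largest 26-connected bright component,
#' then 3D filling of enclosed cavities (internal pores and core are part of
#' the fruit). Fails with "no object found" when the largest bright
#' component covers less than 1 % of the grid.
#'
#' @param vol a [voxel_volume()].
#' @return Logical 3D array, `TRUE` inside the fruit.
#' @export
compute_fruit_mask <- function(vol) {
  stopifnot(is_voxel_volume(vol))
  h <- compute_histogram(vol)
  if (sum(h$counts > 0L) < 2L)
    stop("no object found: volume has a single gray level", call. = FALSE)
  t_otsu <- otsu_threshold(h)
  bright <- vol$intensities >= t_otsu
  if (all(bright))
    stop("no object found: no dark background phase", call. = FALSE)
  lab <- label_components_cpp(bright, dim(bright), 26L)
  if (lab$n == 0L)
    stop("no object found: volume contains no bright phase", call. = FALSE)
  sizes <- tabulate(lab$labels[lab$labels > 0L], lab$n)
  big <- which.max(sizes)
  if (sizes[big] < 0.01 * length(bright))
    stop("no object found: largest bright component is below 1% of the volume",
         call. = FALSE)
  comp <- lab$labels == big
  dim(comp) <- dim(bright)
  fill_holes_cpp(comp, dim(comp))
}

#' Grayscale histogram of a (masked) volume
#'
#' 256 unit-width bins on the 8-bit scale; 1024 bins on the 16-bit scale.
#'
#' @param vol a [voxel_volume()].
#' @param mask optional logical array restricting the counted voxels (e.g.
#'   the fruit mask); must be non-empty.
#' @return A `gray_histogram`: list with `bin_edges`, `mids`, `counts`,
#'   `mask_voxel_count`, `bit_depth`.
#' @export
compute_histogram <- function(vol, mask = NULL) {
  stopifnot(is_voxel_volume(vol))
  v <- vol$intensities
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask", call. = FALSE)
    v <- v[mask]
  }
  nbin <- if (vol$bit_depth == 8L) 256L else 1024L
  width <- 2^vol$bit_depth / nbin
  idx <- pmin(as.integer(v / width), nbin - 1L)
  counts <- tabulate(idx + 1L, nbin)
  edges <- seq(0, 2^vol$bit_depth, by = width)
  structure(list(bin_edges = edges,
                 mids = edges[-length(edges)] + width / 2,
                 counts = counts,
                 mask_voxel_count = length(v),
                 bit_depth = vol$bit_depth),
            class = "gray_histogram")
}

# moving average with partial windows at the ends (keeps all bins defined)
smooth_counts <- function(counts, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(as.numeric(counts))
  half <- (window - 1L) %/% 2L
  n <- length(counts)
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

local_maxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  # strictly above the previous bin, at least level with the next:
  # the first bin of a plateau represents the whole plateau
  which(c(FALSE, s[-1L] > s[-n]) & c(s[-n] >= s[-1L], TRUE))
}

# Otsu's threshold (maximum between-class variance) from a histogram.
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  counts <- as.numeric(hist$counts)
  mids <- hist$mids
  total <- sum(counts)
  if (total == 0) stop("empty histogram", call. = FALSE)
  w0 <- cumsum(counts)
  mu0 <- cumsum(counts * mids)
  mu_t <- mu0[length(mu0)]
  w1 <- total - w0
  between <- (mu_t * w0 - mu0 * total)^2 / (w0 * w1 * total^2)
  between[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(between)
  hist$bin_edges[k + 1L]  # boundary just above the dark class
}

#' Deep-valley global threshold
#'
#' Smooths the histogram with a centered moving average, finds the two
#' highest distinct local maxima (the pore and tissue modes) and places the
#' threshold at the center of the lowest bin strictly between them — the
#' obvious deep valley of a bimodal fruit histogram. Ties take the lowest
#' such bin. If the smoothed histogram has fewer than two maxima (unimodal),
#' the Otsu threshold is returned and `source` is marked `"otsu"`.
#'
#' @param hist a `gray_histogram`, normally computed within the fruit mask.
#' @param smoothing_window odd window width in bins (default 9).
#' @return `list(threshold, smoothing_window, source)` of class
#'   `segmentation_params`.
#' @export
find_valley_threshold <- function(hist, smoothing_window = 9L) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (sum(hist$counts) == 0) stop("empty histogram", call. = FALSE)
  s <- smooth_counts(hist$counts, as.integer(smoothing_window))
  peaks <- local_maxima(s)
  # a mode must carry real mass: sampling-noise wiggles in the tails (below
  # 0.5% of the main mode) are not phases
  peaks <- peaks[s[peaks] >= 0.005 * max(s)]
  params <- function(T, source)
    structure(list(threshold = T, smoothing_window = as.integer(smoothing_window),
                   source = source), class = "segmentation_params")
  if (length(peaks) >= 2L) {
    top2 <- peaks[order(s[peaks], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    if (hi - lo >= 2L) {
      between <- (lo + 1L):(hi - 1L)
      valley <- between[which.min(s[between])]  # which.min takes the lowest tie
      return(params(hist$mids[valley], "valley"))
    }
  }
  params(otsu_threshold(hist), "otsu")
}

#' Segment tissue and pores at a global threshold
#'
#' Inside the fruit mask, voxels with intensity strictly below the threshold
#' are pores (low X-ray attenuation), the rest tissue; outside the mask is
#' background. The strict comparison admits fractional thresholds (such as
#' 69.7 on an integer 8-bit scale) without re-quantization.
#'
#' @param vol a [voxel_volume()].
#' @param params a `segmentation_params` (from [find_valley_threshold()]) or
#'   a single numeric threshold.
#' @param fruit_mask logical array; defaults to [compute_fruit_mask()].
#' @return A `phase_map` (0 background / 1 tissue / 2 pore).
#' @export
segment_phases <- function(vol, params, fruit_mask = NULL) {
  stopifnot(is_voxel_volume(vol))
  T <- if (inherits(params, "segmentation_params")) params$threshold
       else as.numeric(params)
  if (!is.finite(T) || T < 0 || T > 2^vol$bit_depth)
    stop("threshold outside the intensity range", call. = FALSE)
  if (is.null(fruit_mask)) fruit_mask <- compute_fruit_mask(vol)
  phase <- array(0L, dim = dim(vol$intensities))
  phase[fruit_mask] <- 1L
  phase[fruit_mask & vol$intensities < T] <- 2L
  new_phase_map(phase, vol$voxel_size_um, threshold = T)
}
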