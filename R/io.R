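# Volume I/O: multi-page TIFF, directories of numbered TIFF slices, and
# MHD header + raw. Physical voxel size travels in the MHD header
# (ElementSpacing) or, for TIFF, in a flat key-value sidecar file
# ("<path>.meta"); an explicit voxel_size_um argument overrides both.

meta_path <- function(path) paste0(path, ".meta")

write_sidecar <- function(path, vol) {
  lines <- c(sprintf("voxel_size_um = %.17g", vol$voxel_size_um),
             sprintf("bit_depth = %d", vol$bit_depth),
             sprintf("axis_convention = %s", vol$axis_convention))
  writeLines(lines, meta_path(path))
}

read_sidecar <- function(path) {
  mp <- meta_path(path)
  if (!file.exists(mp)) return(NULL)
  lines <- readLines(mp, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  as.list(setNames(vals, keys))
}

guess_format <- function(path) {
  if (dir.exists(path)) return("tiff_dir")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "mhd") return("mhd")
  stop("cannot infer volume format from path: ", path, call. = FALSE)
}

tiff_slice_to_int <- function(m, label) {
  if (length(dim(m)) == 3L) {
    if (dim(m)[3L] != 1L)
      stop("multi-channel TIFF slices are not supported (", label, ")",
           call. = FALSE)
    m <- m[, , 1L]
  }
  storage.mode(m) <- "integer"
  m
}

#' Read a volumetric grayscale image
#'
#' Supported formats: multi-page TIFF, a directory of numbered single-page
#' TIFF slices (ascending numeric order of the digits in the filename), and
#' MHD header + raw. Slices are stacked along the third array dimension in
#' file order, which by the package convention runs calyx end to stem end
#' (the loader cannot verify fruit orientation; record it at scan time).
#'
#' @param path file (or directory) to read.
#' @param format one of "auto", "tiff", "tiff_dir", "mhd".
#' @param voxel_size_um explicit voxel size override in micrometers. Required
#'   when the source carries no voxel size (TIFF without sidecar).
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "tiff_dir", "mhd"),
                        voxel_size_um = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)

  if (format == "mhd") return(read_mhd(path, voxel_size_um))

  if (format == "tiff") {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    slices <- lapply(seq_along(slices), function(i)
      tiff_slice_to_int(slices[[i]], sprintf("%s page %d", path, i)))
  } else { # tiff_dir
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no TIFF slices found in ", path, call. = FALSE)
    num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    ord <- order(is.na(num), num, basename(files))
    files <- files[ord]
    slices <- lapply(files, function(f)
      tiff_slice_to_int(tiff::readTIFF(f, as.is = TRUE), f))
  }

  dims <- vapply(slices, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("inconsistent slice dimensions in ", path, call. = FALSE)
  arr <- array(0L, dim = c(dims[1L, 1L], dims[2L, 1L], length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]

  meta <- read_sidecar(path)
  if (is.null(voxel_size_um)) {
    if (!is.null(meta$voxel_size_um))
      voxel_size_um <- as.numeric(meta$voxel_size_um)
    else
      stop("voxel size not found; pass voxel_size_um explicitly", call. = FALSE)
  }
  axis <- if (!is.null(meta$axis_convention)) meta$axis_convention
          else "slice 1 = calyx end, last slice = stem end"
  bd <- if (!is.null(meta$bit_depth)) as.integer(meta$bit_depth) else NULL
  voxel_volume(arr, voxel_size_um, bit_depth = bd, axis_convention = axis,
               provenance = paste0(format, ":", path))
}

read_mhd <- function(path, voxel_size_um = NULL) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  h <- as.list(setNames(vals, keys))
  if (!is.null(h$NDims) && as.integer(h$NDims) != 3L)
    stop("only 3D MHD volumes are supported", call. = FALSE)
  dims <- as.integer(strsplit(h$DimSize, "\\s+")[[1L]])
  if (length(dims) != 3L) stop("bad DimSize in ", path, call. = FALSE)
  etype <- h$ElementType
  size <- switch(etype, MET_UCHAR = 1L, MET_USHORT = 2L,
                 stop("unsupported ElementType: ", etype, call. = FALSE))
  if (is.null(voxel_size_um) && !is.null(h$ElementSpacing))
    voxel_size_um <- as.numeric(strsplit(h$ElementSpacing, "\\s+")[[1L]][1L])
  if (is.null(voxel_size_um))
    stop("voxel size not found; pass voxel_size_um explicitly", call. = FALSE)
  raw_file <- file.path(dirname(path), h$ElementDataFile)
  if (!file.exists(raw_file))
    stop("raw data file not found: ", raw_file, call. = FALSE)
  n <- prod(dims)
  con <- file(raw_file, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = size, signed = FALSE,
               endian = "little")
  if (length(v) != n)
    stop("raw file shorter than DimSize implies: ", raw_file, call. = FALSE)
  arr <- array(as.integer(v), dim = dims)
  axis <- if (!is.null(h$AnatomicalOrientation)) h$AnatomicalOrientation
          else "slice 1 = calyx end, last slice = stem end"
  voxel_volume(arr, voxel_size_um, bit_depth = if (size == 1L) 8L else 16L,
               axis_convention = axis, provenance = paste0("mhd:", path))
}

#' Write a volumetric grayscale image
#'
#' The written file round-trips bit-identically through [read_volume()].
#' MHD stores the voxel size in its header (ElementSpacing); TIFF formats
#' get a flat key-value sidecar file `<path>.meta`.
#'
#' @param vol a [voxel_volume()].
#' @param path destination file (or directory for "tiff_dir").
#' @param format one of "auto", "tiff", "tiff_dir", "mhd".
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "tiff_dir", "mhd")) {
  stopifnot(is_voxel_volume(vol))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff"
              else if (ext == "mhd") "mhd"
              else "tiff_dir"
  }
  v <- vol$intensities
  maxval <- 2^vol$bit_depth - 1

  if (format == "mhd") {
    raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    header <- c("ObjectType = Image",
                "NDims = 3",
                "BinaryData = True",
                "BinaryDataByteOrderMSB = False",
                sprintf("DimSize = %d %d %d", dim(v)[1L], dim(v)[2L], dim(v)[3L]),
                sprintf("ElementSpacing = %.17g %.17g %.17g",
                        vol$voxel_size_um, vol$voxel_size_um, vol$voxel_size_um),
                sprintf("ElementType = %s",
                        if (vol$bit_depth == 8L) "MET_UCHAR" else "MET_USHORT"),
                sprintf("ElementDataFile = %s", raw_name))
    writeLines(header, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.integer(v), con, size = if (vol$bit_depth == 8L) 1L else 2L,
             endian = "little")
    return(invisible(path))
  }

  slices <- lapply(seq_len(dim(v)[3L]), function(k) v[, , k] / maxval)
  if (format == "tiff") {
    tiff::writeTIFF(slices, path, bits.per.sample = vol$bit_depth)
    write_sidecar(path, vol)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(slices))
      tiff::writeTIFF(slices[[k]], file.path(path, sprintf("slice_%05d.tif", k)),
                      bits.per.sample = vol$bit_depth)
    write_sidecar(path, vol)
  }
  invisible(path)
}
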