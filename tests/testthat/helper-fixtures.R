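# Fixture builders and independent oracles used across the test files.
# Oracles deliberately avoid the package's C++ kernels: the component
# labeler is a plain R breadth-first search, the distance oracle a
# brute-force all-pairs scan.

# digitized ball mask (voxel-center rule), center at the grid middle
fixture_ball <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  co <- arrayInd(seq_len(n^3), c(n, n, n))
  array(rowSums((co - (r + pad + 1))^2) <= r^2, c(n, n, n))
}

# digitized ellipsoid in a given grid
fixture_ellipsoid <- function(dims, center, semi) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  q <- ((co[, 1] - center[1]) / semi[1])^2 +
    ((co[, 2] - center[2]) / semi[2])^2 +
    ((co[, 3] - center[3]) / semi[3])^2
  array(q <= 1, dims)
}

# independent connected-component count: plain breadth-first search
oracle_component_count <- function(mask, conn = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nl <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0L) next
    nl <- nl + 1L
    queue <- i
    lab[i] <- nl
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      co <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        cc <- co + offs[k, ]
        if (all(cc >= 1L) && all(cc <= d)) {
          j <- cc[1L] + d[1L] * (cc[2L] - 1L) + d[1L] * d[2L] * (cc[3L] - 1L)
          if (mask[j] && lab[j] == 0L) { lab[j] <- nl; queue <- c(queue, j) }
        }
      }
    }
  }
  nl
}

# brute-force squared Euclidean distance of every TRUE voxel to the nearest
# FALSE voxel center
oracle_edt_sq <- function(mask) {
  d <- dim(mask)
  out <- array(0, d)
  fg <- which(mask); bg <- which(!mask)
  if (length(fg) == 0L || length(bg) == 0L) return(out)
  cf <- arrayInd(fg, d); cb <- t(arrayInd(bg, d))
  for (i in seq_along(fg))
    out[fg[i]] <- min(colSums((cb - cf[i, ])^2))
  out
}

# wrap a plain integer array as an 8-bit volume
fixture_volume <- function(arr, voxel_size_um = 1) {
  storage.mode(arr) <- "integer"
  voxel_volume(arr, voxel_size_um, bit_depth = 8L)
}

# noise-free two-phase volume from a pore mask
fixture_two_phase <- function(pore, tissue = 160L, pore_val = 30L,
                              voxel_size_um = 1) {
  arr <- array(tissue, dim(pore))
  arr[pore] <- pore_val
  fixture_volume(arr, voxel_size_um)
}

# full-grid phase map from a pore mask (slab geometry, no background)
fixture_phase <- function(pore, voxel_size_um = 1) {
  ph <- array(1L, dim(pore))
  ph[pore] <- 2L
  fruitpore:::new_phase_map(ph, voxel_size_um)
}
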