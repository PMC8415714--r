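# Curve-skeleton pore-network extraction. The pore phase is reduced to a
# one-voxel-thick, topology-preserving filar centerline; skeleton voxels are
# classified by their 26-neighbor count into endpoints, path voxels and
# junctions; junction clusters become pore-body nodes, traced paths between
# nodes become throat edges. Radii come from the Euclidean distance map:
# a node's body radius is the largest inscribed-sphere radius over its
# voxels, a throat's diameter twice the smallest distance-map value along
# the path interior.

#' Skeletonize the pore phase
#'
#' Topology-preserving 3D thinning of the 26-connected pore phase against a
#' 6-connected background: connected components, cavities and tunnels are
#' preserved, and the result is one voxel thick except at junction clusters.
#' Endpoints of one-voxel-wide curves are retained.
#'
#' @param phase a `phase_map` or logical pore array.
#' @return Logical array of skeleton voxels.
#' @export
skeletonize <- function(phase) {
  pore <- if (is_phase_map(phase)) phase$phase == 2L else phase
  thin_cpp(pore, dim(pore))
}

#' Euclidean distance map of the pore phase
#'
#' Exact center-to-center Euclidean distance from every pore voxel to the
#' nearest non-pore voxel, in physical micrometers; zero outside the pore
#' phase. A single isolated pore voxel has distance one voxel.
#'
#' @param phase a `phase_map` or logical pore array.
#' @param voxel_size_um voxel size; taken from the phase map when omitted.
#' @return Numeric array of distances in micrometers.
#' @export
distance_map <- function(phase, voxel_size_um = NULL) {
  if (is_phase_map(phase)) {
    pore <- phase$phase == 2L
    if (is.null(voxel_size_um)) voxel_size_um <- phase$voxel_size_um
  } else {
    pore <- phase
    if (is.null(voxel_size_um)) voxel_size_um <- 1
  }
  sqrt(edt_sq_cpp(pore, dim(pore))) * voxel_size_um
}

# --- voxel-graph machinery -------------------------------------------------

# neighbor table of a skeleton voxel set: for each of the 26 offsets,
# the index (into idx) of that neighbor or NA
skel_adjacency <- function(idx, dims) {
  co <- arrayInd(idx, dims)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  nbr <- matrix(NA_integer_, nrow = length(idx), ncol = nrow(offs))
  for (k in seq_len(nrow(offs))) {
    xx <- co[, 1L] + offs[k, 1L]
    yy <- co[, 2L] + offs[k, 2L]
    zz <- co[, 3L] + offs[k, 3L]
    ok <- xx >= 1L & xx <= nx & yy >= 1L & yy <= ny & zz >= 1L & zz <= nz
    lin <- rep(NA_integer_, length(idx))
    lin[ok] <- xx[ok] + nx * (yy[ok] - 1L) + nx * ny * (zz[ok] - 1L)
    nbr[, k] <- match(lin, idx)
  }
  nbr
}

# union-find over 1..n
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Extract the pore network graph from a skeleton
#'
#' Skeleton voxels with one 26-neighbor are endpoints, with two are path
#' voxels, with three or more junction voxels; 26-adjacent junction voxels
#' merge into a single node at their centroid. Paths traced between nodes
#' become edges. Spur edges (terminating in an endpoint) shorter than
#' `spur_min_um` are removed and the network re-traced until none remain;
#' a connected component shorter than `spur_min_um` in total (e.g. the one-
#' or two-voxel remnant of an isolated round void) collapses to a single
#' isolated node with coordination 0. Closed loops without junctions get one
#' node carrying a self-loop edge.
#'
#' @param skeleton logical array from [skeletonize()].
#' @param dmap distance map from [distance_map()] on the same phase (um).
#' @param voxel_size_um voxel size in micrometers.
#' @param spur_min_um minimum length for an endpoint-terminated edge;
#'   default two voxels.
#' @return A `skeleton_graph`: list with `nodes` (id, x/y/z_um, type,
#'   body_radius_um, degree), `edges` (node_a, node_b, path_length_um,
#'   throat_diameter_um, throat_length_um) and `paths` (list of voxel-index
#'   paths).
#' @export
extract_network <- function(skeleton, dmap, voxel_size_um,
                            spur_min_um = 2 * voxel_size_um) {
  if (!identical(dim(skeleton), dim(dmap)))
    stop("skeleton and distance map have different shapes", call. = FALSE)
  dims <- dim(skeleton)
  skel <- skeleton
  for (iter in seq_len(100L)) {
    g <- trace_network(skel, dmap, dims, voxel_size_um)
    # spur edges: endpoint-terminated and shorter than the threshold,
    # but never a component's only edge (that is the whole structure)
    ends <- g$nodes$degree == 1L
    spur <- with(g$edges, (ends[node_a] | ends[node_b]) &
                   path_length_um < spur_min_um &
                   !(ends[node_a] & ends[node_b]))
    # delete the endpoint-side voxels of each spur (keep far-node voxels)
    drop <- integer(0)
    for (e in which(spur)) {
      a <- g$edges$node_a[e]; b <- g$edges$node_b[e]
      tip <- if (ends[a]) a else b
      path <- g$paths[[e]]
      interior <- setdiff(path, c(g$node_voxels[[a]], g$node_voxels[[b]]))
      drop <- c(drop, interior, g$node_voxels[[tip]])
    }
    # endpoint refinement: digital thinning overruns rounded pore ends (the
    # centerline of a hemispherical cap is a point, but the discrete curve
    # runs to the cap surface, where the distance map falls to one voxel).
    # Retract an endpoint tip while the distance map climbs consistently
    # toward the interior; constant-radius channels are left untouched.
    for (e in seq_len(nrow(g$edges))) {
      if (spur[e]) next
      a <- g$edges$node_a[e]; b <- g$edges$node_b[e]
      path <- g$paths[[e]]
      m <- length(path)
      if (m < 4L) next
      dvals <- dmap[path]
      pc <- arrayInd(path, dim(skel))
      steps <- sqrt(rowSums((pc[-1L, , drop = FALSE] -
                               pc[-m, , drop = FALSE])^2)) * voxel_size_um
      budget <- m - 3L
      retract_k <- function(dv, st, lim) {
        k <- 0L
        while (k < lim && dv[k + 2L] - dv[k + 1L] >= 0.25 * st[k + 1L]) k <- k + 1L
        k
      }
      ka <- if (ends[a]) retract_k(dvals, steps, budget) else 0L
      kb <- if (ends[b]) retract_k(rev(dvals), rev(steps),
                                   max(budget - ka, 0L)) else 0L
      if (ka > 0L) drop <- c(drop, path[seq_len(ka)])
      if (kb > 0L) drop <- c(drop, path[m + 1L - seq_len(kb)])
    }
    if (length(drop) == 0L) break
    skel[unique(drop)] <- FALSE
  }

  # collapse degenerate components: when a component's entire skeleton is
  # shorter than its largest inscribed-sphere radius (or than the spur
  # threshold), it is the thinning remnant of a single round void, not a
  # channel network — it becomes one isolated node at its widest voxel
  if (nrow(g$edges) > 0L) {
    nn <- nrow(g$nodes)
    parent <- seq_len(nn)
    for (e in seq_len(nrow(g$edges))) {
      ra <- uf_find(parent, g$edges$node_a[e])
      rb <- uf_find(parent, g$edges$node_b[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    comp <- vapply(seq_len(nn), function(i) uf_find(parent, i), integer(1))
    ecomp <- comp[g$edges$node_a]
    changed <- FALSE
    for (cc in unique(ecomp)) {
      es <- which(ecomp == cc)
      tot <- sum(g$edges$path_length_um[es])
      maxbr <- max(g$nodes$body_radius_um[comp == cc])
      if (tot < max(maxbr, spur_min_um)) {
        vox <- unique(c(unlist(g$paths[es]),
                        unlist(g$node_voxels[comp == cc])))
        keep <- vox[which.max(dmap[vox])]
        skel[setdiff(vox, keep)] <- FALSE
        changed <- TRUE
      }
    }
    if (changed) g <- trace_network(skel, dmap, dims, voxel_size_um)
  }

  g$node_voxels <- NULL
  structure(g, class = "skeleton_graph")
}

trace_network <- function(skel, dmap, dims, vx) {
  idx <- which(skel)
  if (length(idx) == 0L) {
    return(list(nodes = data.frame(id = integer(0), x_um = numeric(0),
                                   y_um = numeric(0), z_um = numeric(0),
                                   type = character(0),
                                   body_radius_um = numeric(0),
                                   degree = integer(0)),
                edges = data.frame(node_a = integer(0), node_b = integer(0),
                                   path_length_um = numeric(0),
                                   throat_diameter_um = numeric(0),
                                   throat_length_um = numeric(0)),
                paths = list(), node_voxels = list(),
                voxel_size_um = vx))
  }
  nbr <- skel_adjacency(idx, dims)
  deg <- rowSums(!is.na(nbr))
  nvox <- length(idx)
  co <- arrayInd(idx, dims)

  # node voxels: everything that is not a plain path voxel
  is_node_vox <- deg != 2L
  node_of <- rep(NA_integer_, nvox)

  # merge 26-adjacent junction voxels (deg >= 3) into clusters
  jv <- which(deg >= 3L)
  parent <- seq_len(nvox)
  for (i in jv) {
    for (j in nbr[i, ]) {
      if (!is.na(j) && deg[j] >= 3L) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  next_node <- 0L
  node_voxels <- list()
  if (length(jv) > 0L) {
    roots <- vapply(jv, function(i) uf_find(parent, i), integer(1))
    for (r in unique(roots)) {
      next_node <- next_node + 1L
      vs <- jv[roots == r]
      node_voxels[[next_node]] <- idx[vs]
      node_of[vs] <- next_node
    }
  }
  for (i in which(deg <= 1L)) {
    next_node <- next_node + 1L
    node_voxels[[next_node]] <- idx[i]
    node_of[i] <- next_node
  }

  # trace paths from every node voxel through degree-2 voxels
  edges_a <- integer(0); edges_b <- integer(0)
  paths <- list()
  visited_pv <- rep(FALSE, nvox)        # consumed path voxels
  used_direct <- character(0)           # node-voxel pairs already linked

  emit_edge <- function(na, nb, path_vox_ids) {
    edges_a <<- c(edges_a, na)
    edges_b <<- c(edges_b, nb)
    paths[[length(paths) + 1L]] <<- idx[path_vox_ids]
  }

  for (s in which(is_node_vox)) {
    for (m in nbr[s, ]) {
      if (is.na(m)) next
      if (is_node_vox[m]) {
        # direct node-node adjacency; skip intra-cluster, dedupe pairs
        if (node_of[m] == node_of[s]) next
        key <- paste(min(s, m), max(s, m))
        if (key %in% used_direct) next
        used_direct <- c(used_direct, key)
        emit_edge(node_of[s], node_of[m], c(s, m))
      } else if (!visited_pv[m]) {
        # walk the degree-2 chain
        chain <- c(s, m)
        visited_pv[m] <- TRUE
        prev <- s; cur <- m
        repeat {
          nxt <- nbr[cur, ]
          nxt <- nxt[!is.na(nxt) & nxt != prev]
          # at a corner a path voxel can see both the previous voxel and a
          # node voxel adjacent to it; prefer unvisited continuation
          if (length(nxt) > 1L) {
            cand <- nxt[is_node_vox[nxt] | !visited_pv[nxt]]
            if (length(cand) > 0L) nxt <- cand
            nxt <- nxt[1L]
          } else if (length(nxt) == 0L) {
            break  # dead end (shouldn't happen: endpoints are node voxels)
          } else nxt <- nxt[1L]
          chain <- c(chain, nxt)
          if (is_node_vox[nxt]) break
          if (visited_pv[nxt]) break   # closed loop back into the chain
          visited_pv[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        last <- chain[length(chain)]
        if (is_node_vox[last]) {
          emit_edge(node_of[s], node_of[last], chain)
        }
      }
    }
  }

  # pure cycles with no node voxel: collapse each to one self-loop node
  remaining <- which(!is_node_vox & !visited_pv)
  if (length(remaining) > 0L) {
    sub_parent <- seq_len(nvox)
    for (i in remaining) for (j in nbr[i, ]) {
      if (!is.na(j) && !is_node_vox[j] && !visited_pv[j]) {
        ri <- uf_find(sub_parent, i); rj <- uf_find(sub_parent, j)
        if (ri != rj) sub_parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(remaining, function(i) uf_find(sub_parent, i), integer(1))
    for (r in unique(roots)) {
      vs <- remaining[roots == r]
      next_node <- next_node + 1L
      node_voxels[[next_node]] <- idx[vs[1L]]
      node_of[vs[1L]] <- next_node
      # walk the cycle in adjacency order so the path length is real
      start <- vs[1L]
      chain <- start
      prev <- NA_integer_; cur <- start
      repeat {
        nxt <- nbr[cur, ]
        nxt <- nxt[!is.na(nxt) & nxt %in% vs]
        nxt <- nxt[is.na(prev) | nxt != prev]
        if (length(nxt) == 0L) break
        nxt <- nxt[1L]
        if (nxt == start) { chain <- c(chain, start); break }
        chain <- c(chain, nxt)
        prev <- cur; cur <- nxt
      }
      emit_edge(next_node, next_node, chain)
    }
  }

  n_nodes <- next_node
  deg_node <- tabulate(c(edges_a, edges_b), n_nodes)  # self-loops count twice
  # collapse sub-spur-length whole components of a single edge between two
  # endpoints (thinning remnants of round isolated voids) handled by caller
  # via spur rules; here, degree-0 single voxels are isolated nodes already

  node_xyz <- t(vapply(seq_len(n_nodes), function(k) {
    vs <- match(node_voxels[[k]], idx)
    colMeans(co[vs, , drop = FALSE]) - 0.5
  }, numeric(3)))
  body_r <- vapply(seq_len(n_nodes), function(k)
    max(dmap[node_voxels[[k]]]), numeric(1))
  type <- ifelse(deg_node == 0L, "isolated",
                 ifelse(deg_node == 1L, "endpoint", "junction"))

  nodes <- data.frame(id = seq_len(n_nodes),
                      x_um = node_xyz[, 1L] * vx,
                      y_um = node_xyz[, 2L] * vx,
                      z_um = node_xyz[, 3L] * vx,
                      type = type,
                      body_radius_um = body_r,
                      degree = deg_node)

  # edge metrics
  ne <- length(edges_a)
  plen <- numeric(ne); tdia <- numeric(ne); tlen <- numeric(ne)
  if (ne > 0L) for (e in seq_len(ne)) {
    p <- paths[[e]]
    pc <- arrayInd(p, dims)
    steps <- sqrt(rowSums((pc[-1L, , drop = FALSE] -
                             pc[-nrow(pc), , drop = FALSE])^2))
    plen[e] <- sum(steps) * vx
    interior <- if (length(p) > 2L) p[-c(1L, length(p))] else p
    tdia[e] <- 2 * min(dmap[interior])
    tlen[e] <- max(plen[e] - nodes$body_radius_um[edges_a[e]] -
                     nodes$body_radius_um[edges_b[e]], 0)
  }
  edges <- data.frame(node_a = edges_a, node_b = edges_b,
                      path_length_um = plen,
                      throat_diameter_um = tdia,
                      throat_length_um = tlen)
  list(nodes = nodes, edges = edges, paths = paths,
       node_voxels = node_voxels, voxel_size_um = vx)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes (%d junctions, %d endpoints, %d isolated), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "junction"),
              sum(x$nodes$type == "endpoint"), sum(x$nodes$type == "isolated"),
              nrow(x$edges)))
  invisible(x)
}

#' Pore-network morphometrics
#'
#' Averages over the network: throat length and diameter over all edges;
#' pore length as the mean body diameter (twice the inscribed-sphere radius)
#' over all nodes; coordination number (incident throat count) averaged over
#' all nodes including isolated ones — a pore space of disconnected round
#' voids therefore has average and largest coordination 0.
#'
#' @param graph a `skeleton_graph`.
#' @return `list(avg_throat_length_um, avg_throat_diameter_um,
#'   avg_pore_length_um, avg_coordination, max_coordination, n_nodes,
#'   n_edges)`.
#' @export
network_stats <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nn <- nrow(graph$nodes); ne <- nrow(graph$edges)
  if (nn == 0L)
    return(list(avg_throat_length_um = 0, avg_throat_diameter_um = 0,
                avg_pore_length_um = 0, avg_coordination = 0,
                max_coordination = 0L, n_nodes = 0L, n_edges = 0L))
  list(avg_throat_length_um = if (ne > 0L) mean(graph$edges$throat_length_um) else 0,
       avg_throat_diameter_um = if (ne > 0L) mean(graph$edges$throat_diameter_um) else 0,
       avg_pore_length_um = mean(2 * graph$nodes$body_radius_um),
       avg_coordination = mean(graph$nodes$degree),
       max_coordination = max(graph$nodes$degree),
       n_nodes = nn, n_edges = ne)
}
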