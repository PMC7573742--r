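# Shared fixtures (built once per test run) and independent oracles.

# Small anatomy reused across tests: 20^3 grid, 6 nodes, 4 reference
# subjects. Kept deliberately small so unit tests stay fast.
tiny_anatomy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      parc <- generate_parcellation(c(20L, 20L, 20L), n_nodes = 6L, seed = 42L)
      atlas <- generate_reference_paths(parc, n_reference = 4L,
                                        jitter_sd = 0.5, seed = 43L)
      cache <<- list(parcellation = parc, atlas = atlas,
                     territory = left_hemisphere_territory(parc))
    }
    cache
  }
})

# A hand-made atlas on a small grid from explicit path specifications:
# paths = list("i|j" = list(list(vox=..., p=...), ...)).
manual_atlas <- function(n_nodes, grid_shape, paths) {
  structure(list(n_nodes = n_nodes,
                 n_reference = max(lengths(paths)),
                 grid_shape = as.integer(grid_shape), paths = paths),
            class = "ref_path_atlas")
}

manual_lesion <- function(grid_shape, voxels, subject_id = "toy") {
  m <- array(0L, grid_shape)
  m[voxels] <- 1L
  lesion_mask(m, subject_id)
}

# "i|j" edge ids straight from a pair matrix.
edge_id_test <- function(ep) paste(ep[, 1L], ep[, 2L], sep = "|")

# Column-major 1-based coordinate -> linear index, written out by hand.
coord_to_linear_test <- function(co, dims) {
  co[, 1L] + (co[, 2L] - 1L) * dims[1L] + (co[, 3L] - 1L) * dims[1L] * dims[2L]
}

# Independent connected-component oracle: repeated set expansion over an
# explicit voxel adjacency test (no igraph, no package labeling code).
brute_components <- function(voxels, dims, connectivity = 26) {
  co <- arrayInd(voxels, dims)
  adjacent <- function(a, b) {
    d <- abs(co[a, ] - co[b, ])
    lim <- c(`6` = 1, `18` = 2, `26` = 3)[[as.character(connectivity)]]
    max(d) <= 1 && sum(d) <= lim && any(d > 0)
  }
  n <- length(voxels)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) for (o in seq_len(n)) {
        if (comp[o] == 0L && adjacent(f, o)) {
          comp[o] <- cur
          nxt <- c(nxt, o)
        }
      }
      frontier <- nxt
    }
  }
  comp
}

# Independent maximally-weighted connected subgraph oracle: exhaustive
# enumeration over all non-empty edge subsets, keeping those whose induced
# graph is connected (checked by hand-rolled reachability).
brute_max_connected_subgraph <- function(edges) {
  m <- nrow(edges)
  if (m == 0L) return(list(total = 0, edges = integer(0)))
  best <- -Inf
  best_set <- integer(0)
  for (mask in seq_len(2^m - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    ei <- edges$node_i[sel]
    ej <- edges$node_j[sel]
    nodes <- unique(c(ei, ej))
    reach <- nodes[1L]
    repeat {
      add <- unique(c(ej[ei %in% reach], ei[ej %in% reach]))
      add <- setdiff(add, reach)
      if (!length(add)) break
      reach <- c(reach, add)
    }
    if (length(reach) < length(nodes)) next
    tot <- sum(edges$weight[sel])
    if (tot > best) {
      best <- tot
      best_set <- sel
    }
  }
  list(total = best, edges = best_set)
}
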