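# Internal helpers shared across modules: seeded evaluation, voxel-grid
# geometry and connected-component labeling.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# sample() without the length-1 surprise
sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Neighborhood offsets for a 3-D connectivity scheme
#'
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full cube).
#' @return Integer matrix, one row per offset.
#' @keywords internal
connectivity_offsets <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[[as.character(connectivity)]]
  g[rowSums(abs(g)) <= lim, , drop = FALSE]
}

# Linear-index <-> coordinate helpers (1-based, column-major as in R arrays).
coord_to_linear <- function(co, dims) {
  co[, 1L] + (co[, 2L] - 1L) * dims[1L] + (co[, 3L] - 1L) * dims[1L] * dims[2L]
}

#' Neighbors of a voxel set
#'
#' Linear indices of all grid neighbors of `idx` under the given
#' connectivity, bounds-checked (the result may overlap `idx` itself for
#' multi-voxel input).
#'
#' @param idx Linear voxel indices (1-based, column-major).
#' @param dims Grid dimensions (integer triple).
#' @param connectivity 6, 18 or 26.
#' @return Linear indices of neighboring voxels.
#' @export
voxel_neighbors <- function(idx, dims, connectivity = 26) {
  if (!length(idx)) return(integer(0))
  off <- connectivity_offsets(connectivity)
  co <- arrayInd(idx, dims)
  out <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- sweep(co, 2L, off[k, ], "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    out[[k]] <- coord_to_linear(nb[ok, , drop = FALSE], dims)
  }
  unique(unlist(out))
}

#' Label connected components of a 3-D logical/numeric volume
#'
#' Components are defined under 6-, 18- or 26-connectivity. Used for cluster
#' extraction in the voxel maps and for validating synthetic lesion blobs.
#'
#' @param mask 3-D array; nonzero voxels are foreground.
#' @param connectivity One of 6, 18, 26 (default 26, the most permissive and
#'   the lesion-mapping convention for "contiguous").
#' @return List with `index` (linear indices of foreground voxels), `labels`
#'   (component id per foreground voxel) and `n` (number of components).
#' @export
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  idx <- which(mask != 0)
  if (!length(idx)) return(list(index = integer(0), labels = integer(0), n = 0L))
  # half-neighborhood so each undirected adjacency is generated once
  off <- connectivity_offsets(connectivity)
  keep <- off[, 1L] * 1L + off[, 2L] * 4L + off[, 3L] * 16L > 0L
  off <- off[keep, , drop = FALSE]
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, dims)
  efrom <- eto <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- sweep(co, 2L, off[k, ], "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    lin <- coord_to_linear(nb[ok, , drop = FALSE], dims)
    hit <- pos[lin] > 0L
    efrom[[k]] <- which(ok)[hit]
    eto[[k]] <- pos[lin[hit]]
  }
  ef <- unlist(efrom)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, rbind(ef, unlist(eto)))
  comp <- igraph::components(g)
  list(index = idx, labels = as.integer(comp$membership), n = comp$no)
}

# Precomputed geometry for hot accretion loops: linear-index deltas of the
# 26-neighborhood plus an interior flag so interior voxels skip bounds
# checks entirely.
grid_geometry <- function(dims) {
  off <- connectivity_offsets(26)
  deltas <- as.integer(off %*% c(1L, dims[1L], dims[1L] * dims[2L]))
  nv <- prod(dims)
  co <- arrayInd(seq_len(nv), dims)
  interior <- co[, 1L] > 1L & co[, 1L] < dims[1L] &
    co[, 2L] > 1L & co[, 2L] < dims[2L] &
    co[, 3L] > 1L & co[, 3L] < dims[3L]
  list(dims = dims, deltas = deltas, interior = interior)
}

neighbors26 <- function(v, geom) {
  if (geom$interior[v]) return(v + geom$deltas)
  voxel_neighbors(v, geom$dims, 26)
}

# Ordered upper-triangle node pairs (i < j), the fixed edge vectorization
# convention: (1,2),(1,3),...,(1,n),(2,3),...
edge_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes))
  cbind(i = i, j = j)
}

edge_id <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")

#' Devectorize an edge vector into a symmetric node-by-node matrix
#'
#' Inverse of the fixed upper-triangle vectorization used by
#' [batch_disconnectomes()]. Diagonal is set to 0.
#'
#' @param vec Values in edge-pair order (see [edge_pairs()]), or a named
#'   vector with "i|j" names covering a subset of pairs.
#' @param n_nodes Number of nodes.
#' @param fill Value for pairs absent from `vec` (default `NA`).
#' @return Symmetric `n_nodes` x `n_nodes` matrix.
#' @export
devectorize_edges <- function(vec, n_nodes, fill = NA_real_) {
  m <- matrix(fill, n_nodes, n_nodes)
  diag(m) <- 0
  ep <- edge_pairs(n_nodes)
  if (!is.null(names(vec))) {
    ids <- edge_id(ep[, 1L], ep[, 2L])
    hit <- match(names(vec), ids)
    stopifnot(!anyNA(hit))
    for (k in seq_along(vec)) {
      m[ep[hit[k], 1L], ep[hit[k], 2L]] <- vec[k]
      m[ep[hit[k], 2L], ep[hit[k], 1L]] <- vec[k]
    }
  } else {
    stopifnot(length(vec) == nrow(ep))
    m[ep] <- vec
    m[ep[, 2:1]] <- vec
  }
  m
}

#' Vectorize a symmetric matrix into the fixed upper-triangle edge order
#' @param m Symmetric matrix.
#' @return Named vector in [edge_pairs()] order.
#' @export
vectorize_edges <- function(m) {
  n <- nrow(m)
  ep <- edge_pairs(n)
  v <- m[ep]
  names(v) <- edge_id(ep[, 1L], ep[, 2L])
  v
}
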