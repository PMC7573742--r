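# Disconnectome construction: intersecting a lesion mask with a reference
# path atlas yields, per node pair, the proportional loss of shortest-path
# probability — 0 (no disconnection) to 1 (complete disconnection).

#' Per-edge structural disconnection for one lesion
#'
#' For each node pair and reference subject, the loss is the summed path
#' probability over lesioned voxels divided by the total path probability
#' for that pair; the pair's disconnection value is the mean loss across
#' reference subjects. Pairs with zero total reference probability are set
#' to 0 and flagged unconnected.
#'
#' @param lesion A `lesion_mask` on the atlas grid.
#' @param atlas A `ref_path_atlas`.
#' @return Object of class `disconnectome`: `subject_id`, `n_nodes`,
#'   `values` (symmetric matrix in [0, 1], zero diagonal) and an
#'   `unconnected` attribute (logical per pair, "i|j" named).
#' @export
edge_disconnection <- function(lesion, atlas) {
  stopifnot(inherits(lesion, "lesion_mask"), inherits(atlas, "ref_path_atlas"))
  if (!identical(dim(lesion$mask), as.integer(atlas$grid_shape)) &&
      !identical(as.integer(dim(lesion$mask)), as.integer(atlas$grid_shape)))
    stop("lesion grid ", paste(dim(lesion$mask), collapse = "x"),
         " does not match atlas grid ",
         paste(atlas$grid_shape, collapse = "x"))
  les <- as.logical(lesion$mask)
  nn <- atlas$n_nodes
  vals <- matrix(0, nn, nn)
  unconnected <- logical(length(atlas$paths))
  names(unconnected) <- names(atlas$paths)
  ep <- edge_pairs(nn)
  for (k in seq_len(nrow(ep))) {
    refs <- atlas$paths[[edge_id(ep[k, 1L], ep[k, 2L])]]
    totals <- vapply(refs, function(rf) sum(rf$p), numeric(1))
    if (is.null(refs) || !length(refs) || all(totals <= 0)) {
      unconnected[k] <- TRUE
      next
    }
    losses <- vapply(seq_along(refs), function(r) {
      if (totals[r] <= 0) return(0)
      sum(refs[[r]]$p[les[refs[[r]]$vox]]) / totals[r]
    }, numeric(1))
    v <- mean(losses)
    vals[ep[k, 1L], ep[k, 2L]] <- v
    vals[ep[k, 2L], ep[k, 1L]] <- v
  }
  structure(list(subject_id = lesion$subject_id, n_nodes = nn,
                 values = vals, unconnected = unconnected),
            class = "disconnectome")
}

#' @export
print.disconnectome <- function(x, ...) {
  cat("disconnectome", x$subject_id, "-", x$n_nodes, "nodes; mean edge loss",
      round(mean(vectorize_edges(x$values)), 4), "\n")
  invisible(x)
}

#' Stack per-subject disconnectomes into a subjects x edges matrix
#'
#' Columns follow the fixed lexicographic upper-triangle order
#' (1,2),(1,3),...,(2,3),... and are named "i|j"; row order matches the
#' subject order of `lesions`.
#'
#' @param lesions List of `lesion_mask` objects.
#' @param atlas A `ref_path_atlas`.
#' @return Numeric matrix with an `unconnected` attribute marking pairs
#'   with no reference connectivity.
#' @export
batch_disconnectomes <- function(lesions, atlas) {
  rows <- lapply(lesions, function(l) {
    d <- edge_disconnection(l, atlas)
    list(v = vectorize_edges(d$values), u = d$unconnected)
  })
  m <- do.call(rbind, lapply(rows, `[[`, "v"))
  rownames(m) <- vapply(lesions, `[[`, "", "subject_id")
  attr(m, "unconnected") <- rows[[1L]]$u
  m
}

#' Edge inclusion mask at the group level
#'
#' An edge counts as "lesioned" for a subject when its disconnection value
#' exceeds `min_disconnect` (strictly; default 0, i.e. any nonzero loss).
#' Inclusion uses the same floor rule as the voxel coverage mask.
#'
#' @param edge_matrix Subjects x edges disconnection matrix.
#' @param n_subjects Cohort size (default `nrow(edge_matrix)`).
#' @param min_fraction Inclusion fraction (default 0.10).
#' @param min_disconnect Per-subject disconnection floor (default 0).
#' @return Named logical vector over edges.
#' @export
edge_coverage_mask <- function(edge_matrix, n_subjects = nrow(edge_matrix),
                               min_fraction = 0.10, min_disconnect = 0) {
  counts <- colSums(edge_matrix > min_disconnect)
  keep <- coverage_mask(counts, n_subjects, min_fraction)
  unc <- attr(edge_matrix, "unconnected")
  if (!is.null(unc)) keep <- keep & !unc[colnames(edge_matrix)]
  keep
}

#' Cumulative disconnection of a node region
#'
#' Sums disconnection over all unique edges with at least one endpoint in
#' `region_nodes` (each edge counted once). Used as the "localizer"
#' nuisance covariate: total disconnection of the regions implicated by the
#' voxel analysis.
#'
#' @param disconnectome A `disconnectome`.
#' @param region_nodes Non-empty set of node ids in `1..n_nodes`.
#' @return Scalar cumulative disconnection.
#' @export
cumulative_region_disconnection <- function(disconnectome, region_nodes) {
  stopifnot(inherits(disconnectome, "disconnectome"))
  region_nodes <- unique(as.integer(region_nodes))
  if (!length(region_nodes)) stop("region_nodes is empty")
  if (any(region_nodes < 1L | region_nodes > disconnectome$n_nodes))
    stop("region_nodes outside 1..n_nodes")
  ep <- edge_pairs(disconnectome$n_nodes)
  touch <- ep[, 1L] %in% region_nodes | ep[, 2L] %in% region_nodes
  sum(disconnectome$values[ep[touch, , drop = FALSE]])
}

# Cumulative region disconnection per subject straight from an edge matrix.
cumulative_region_disconnection_matrix <- function(edge_matrix, region_nodes,
                                                   n_nodes) {
  region_nodes <- unique(as.integer(region_nodes))
  if (!length(region_nodes)) stop("region_nodes is empty")
  ep <- edge_pairs(n_nodes)
  touch <- ep[, 1L] %in% region_nodes | ep[, 2L] %in% region_nodes
  ids <- edge_id(ep[touch, 1L], ep[touch, 2L])
  rowSums(edge_matrix[, intersect(ids, colnames(edge_matrix)), drop = FALSE])
}
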