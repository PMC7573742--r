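# Voxel-level SVR lesion-symptom mapping: coverage masking, direct total
# lesion volume control, permutation z-maps, threshold + cluster-extent
# filtering and atlas labeling.

#' Voxelwise lesion overlap map
#'
#' @param lesions List of `lesion_mask` objects on a common grid.
#' @return Integer 3-D array: per-voxel count of subjects lesioned there.
#' @export
lesion_overlap_map <- function(lesions) {
  stopifnot(length(lesions) >= 1L)
  dims <- dim(lesions[[1L]]$mask)
  acc <- array(0L, dims)
  for (l in lesions) {
    if (!identical(dim(l$mask), dims))
      stop("lesion grid mismatch for subject ", l$subject_id, ": ",
           paste(dim(l$mask), collapse = "x"), " vs ",
           paste(dims, collapse = "x"))
    acc <- acc + (l$mask != 0L)
  }
  acc
}

#' Minimum-coverage inclusion mask
#'
#' A voxel (or edge) enters the group analysis only if it is lesioned in at
#' least `min_fraction` of the cohort. The count threshold is
#' `floor(min_fraction * n)` — the floor rule reproduces the conventional
#' printed inclusion counts (5 of 57 and 4 of 41 at 10%) — guarded below by
#' 1 so tiny cohorts never admit never-lesioned features.
#'
#' @param overlap Integer volume (or vector) of per-feature lesion counts.
#' @param n_subjects Cohort size.
#' @param min_fraction Inclusion fraction in (0, 1), default 0.10.
#' @return Logical array/vector of included features.
#' @export
coverage_mask <- function(overlap, n_subjects, min_fraction = 0.10) {
  if (min_fraction <= 0 || min_fraction >= 1)
    stop("min_fraction must be in (0, 1)")
  overlap >= coverage_threshold(n_subjects, min_fraction)
}

#' @rdname coverage_mask
#' @return `coverage_threshold`: the integer count threshold.
#' @export
coverage_threshold <- function(n_subjects, min_fraction = 0.10) {
  max(1L, as.integer(floor(min_fraction * n_subjects)))
}

#' Direct total lesion volume control (dTLVC)
#'
#' Scales subject `i`'s binary lesion row by `1 / sqrt(volume_i)` so every
#' subject's lesion vector has unit Euclidean norm, removing the mechanical
#' effect of lesion size on the multivariate fit. By default the volume is
#' the row sum of the given matrix; pass `volumes` explicitly (e.g. total
#' lesion volume over the whole grid) when the matrix holds only the
#' coverage-masked voxel subset.
#'
#' @param lesion_matrix Subjects x voxels binary matrix.
#' @param volumes Per-subject scaling volumes (default `rowSums`).
#' @return Real matrix with scaled rows.
#' @export
dtlvc_scale <- function(lesion_matrix, volumes = rowSums(lesion_matrix)) {
  lesion_matrix <- as.matrix(lesion_matrix)
  if (any(volumes <= 0)) {
    bad <- which(volumes <= 0)
    nm <- rownames(lesion_matrix)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("dTLVC undefined for subject(s) with empty lesion: ",
         paste(nm, collapse = ", "))
  }
  lesion_matrix / sqrt(volumes)
}

#' Desk-scale cluster-extent criterion
#'
#' The full-resolution analysis drops clusters below 500 contiguous 1 mm^3
#' voxels; on a toy grid the criterion scales with grid volume (relative to
#' a 181 x 217 x 181 1-mm reference grid) with a floor of 5 voxels, so toy
#' analyses behave analogously.
#'
#' @param grid_shape Integer triple.
#' @param reference_min Full-resolution criterion (500 voxels).
#' @param reference_volume Full-resolution grid volume.
#' @param floor_voxels Smallest admissible criterion.
#' @return Integer minimum cluster size.
#' @export
scale_min_cluster <- function(grid_shape, reference_min = 500L,
                              reference_volume = 181L * 217L * 181L,
                              floor_voxels = 5L) {
  max(as.integer(floor_voxels),
      as.integer(round(reference_min * prod(grid_shape) / reference_volume)))
}

#' Threshold a z-map and extract surviving clusters
#'
#' Keeps voxels with `z < z_thresh` (strict, one-tailed for negative
#' associations), labels connected components under the configured
#' connectivity, and drops components smaller than `min_cluster`.
#'
#' @param z Real 3-D array of z-scores (may contain NA outside the mask).
#' @param mask Logical array of analyzed voxels.
#' @param z_thresh Threshold, default -1.65 (P < 0.05 one-tailed).
#' @param min_cluster Minimum cluster extent in voxels (>= 1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List of clusters sorted by decreasing size, each with
#'   `cluster_id`, `voxels` (linear indices), `size`, `peak_z` (most
#'   negative z), `peak_coordinate` and `center_of_mass` (unweighted mean
#'   voxel coordinate, 1-based).
#' @export
threshold_and_cluster <- function(z, mask, z_thresh = -1.65, min_cluster = 1L,
                                  connectivity = 26) {
  stopifnot(min_cluster >= 1L, identical(dim(z), dim(mask)))
  dims <- dim(z)
  sig <- array(FALSE, dims)
  sig[which(mask)] <- !is.na(z[which(mask)]) & z[which(mask)] < z_thresh
  comp <- label_components(sig, connectivity)
  if (!comp$n) return(list())
  clusters <- lapply(seq_len(comp$n), function(k) {
    vox <- comp$index[comp$labels == k]
    if (length(vox) < min_cluster) return(NULL)
    zv <- z[vox]
    peak <- vox[which.min(zv)]
    co <- arrayInd(vox, dims)
    list(cluster_id = NA_integer_, voxels = vox, size = length(vox),
         peak_z = min(zv),
         peak_coordinate = as.integer(arrayInd(peak, dims)),
         center_of_mass = colMeans(co))
  })
  clusters <- Filter(Negate(is.null), clusters)
  clusters <- clusters[order(vapply(clusters, `[[`, 0L, "size"),
                             decreasing = TRUE)]
  for (k in seq_along(clusters)) clusters[[k]]$cluster_id <- k
  clusters
}

#' Run the full SVR-VLSM analysis
#'
#' Composes the pipeline: lesion overlap -> coverage mask -> dTLVC scaling
#' (by each subject's total lesion volume) -> permutation-z-scored SVR
#' weight map -> threshold and cluster-extent filtering.
#'
#' @param lesions List of `lesion_mask` objects.
#' @param target `residual_scores` or numeric vector aligned to `lesions`.
#' @param config An `svr_config`.
#' @param min_lesion_frac Coverage inclusion fraction (default 0.10).
#' @param z_thresh Voxelwise threshold (default -1.65).
#' @param min_cluster Minimum cluster extent; `NULL` (default) uses the
#'   desk-scale rule of [scale_min_cluster()].
#' @param connectivity Cluster connectivity (default 26).
#' @return Object of class `voxel_stat_map`: `grid_shape`, `in_mask`
#'   (logical volume), `z` (real volume, NA outside the mask), `clusters`
#'   (surviving clusters only), `weight_map`, `overlap`, and the thresholds
#'   used.
#' @export
run_vlsm <- function(lesions, target, config = svr_config(),
                     min_lesion_frac = 0.10, z_thresh = -1.65,
                     min_cluster = NULL, connectivity = 26) {
  y <- as_target(target)
  n <- length(lesions)
  if (n != length(y)) stop("subjects misaligned between lesions and target")
  dims <- dim(lesions[[1L]]$mask)
  if (is.null(min_cluster)) min_cluster <- scale_min_cluster(dims)
  overlap <- lesion_overlap_map(lesions)
  mask <- coverage_mask(overlap, n, min_lesion_frac)
  mask_idx <- which(mask)
  if (!length(mask_idx))
    stop("coverage mask is empty at min_lesion_frac = ", min_lesion_frac)
  volumes <- vapply(lesions, `[[`, 0L, "volume")
  X <- t(vapply(lesions, function(l) as.numeric(l$mask[mask_idx]),
                numeric(length(mask_idx))))
  X <- dtlvc_scale(X, volumes = volumes)
  colnames(X) <- as.character(mask_idx)
  wm <- permutation_zscores(X, y, config)
  zvol <- array(NA_real_, dims)
  zvol[mask_idx] <- wm$z_scores
  clusters <- threshold_and_cluster(zvol, mask, z_thresh, min_cluster,
                                    connectivity)
  structure(list(
    grid_shape = dims, in_mask = mask, z = zvol, clusters = clusters,
    weight_map = wm, overlap = overlap, n_subjects = n,
    z_thresh = z_thresh, min_cluster = min_cluster,
    connectivity = connectivity, min_lesion_frac = min_lesion_frac
  ), class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat("voxel_stat_map:", sum(x$in_mask), "voxels in mask;",
      length(x$clusters), "cluster(s) surviving z <", x$z_thresh,
      "and extent >=", x$min_cluster, "\n")
  invisible(x)
}

#' Label surviving clusters against a parcellation
#'
#' One row per (cluster, node) intersection with the voxel count, the
#' within-node peak z and the unweighted center of mass of the
#' intersection; background voxels are excluded. Rows are sorted by node
#' id within cluster.
#'
#' @param map A `voxel_stat_map`.
#' @param parcellation A `parcellation` on the same grid.
#' @return Data frame with columns `cluster_id`, `node_id`, `node_name`,
#'   `com_x`, `com_y`, `com_z`, `peak_z`, `n_voxels`.
#' @export
label_clusters <- function(map, parcellation) {
  stopifnot(identical(map$grid_shape, parcellation$grid_shape))
  rows <- list()
  for (cl in map$clusters) {
    labs <- parcellation$labels[cl$voxels]
    for (nd in sort(unique(labs[labs > 0L]))) {
      vox <- cl$voxels[labs == nd]
      co <- arrayInd(vox, map$grid_shape)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, node_id = nd,
        node_name = parcellation$node_names[nd],
        com_x = mean(co[, 1L]), com_y = mean(co[, 2L]), com_z = mean(co[, 3L]),
        peak_z = min(map$z[vox]), n_voxels = length(vox),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    return(data.frame(cluster_id = integer(0), node_id = integer(0),
                      node_name = character(0), com_x = numeric(0),
                      com_y = numeric(0), com_z = numeric(0),
                      peak_z = numeric(0), n_voxels = integer(0)))
  do.call(rbind, rows)
}
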