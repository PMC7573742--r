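# Standard-format I/O: NIfTI volumes for masks and maps, TSV for tables
# and matrices, YAML for run configuration, JSON manifests for provenance.
# Voxel coordinates in exported tables are 0-based and dimension-ordered;
# in-memory R structures stay 1-based (R array convention).

#' Read / write lesion masks as NIfTI
#'
#' @param path File path (.nii or .nii.gz).
#' @param subject_id Identifier for the returned mask.
#' @return `read_lesion_nifti`: a `lesion_mask`.
#' @export
read_lesion_nifti <- function(path, subject_id = sub("\\.nii(\\.gz)?$", "",
                                                     basename(path))) {
  vol <- RNifti::readNifti(path)
  arr <- array(as.integer(as.array(vol) != 0), dim(vol))
  new_lesion_mask(arr, subject_id)
}

#' @rdname read_lesion_nifti
#' @param lesion A `lesion_mask`.
#' @export
write_lesion_nifti <- function(lesion, path) {
  RNifti::writeNifti(array(as.integer(lesion$mask), dim(lesion$mask)), path)
  invisible(path)
}

#' Write a real-valued volume (e.g. overlap or z map) as NIfTI
#' @param volume 3-D numeric array.
#' @param path Output path.
#' @export
write_volume_nifti <- function(volume, path) {
  RNifti::writeNifti(volume, path)
  invisible(path)
}

#' Read / write behavior tables as TSV
#' @param path File path.
#' @return `read_behavior_tsv`: a validated `behavior_table`.
#' @export
read_behavior_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(subject_id = "character"))
  validate_behavior_table(tab)
  tab
}

#' @rdname read_behavior_tsv
#' @param tab A behavior table.
#' @export
write_behavior_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a disconnectome as a TSV matrix with node-name headers
#' @param disconnectome A `disconnectome`.
#' @param path Output path.
#' @param node_names Optional node names (default node ids).
#' @export
write_disconnectome_tsv <- function(disconnectome, path, node_names = NULL) {
  m <- disconnectome$values
  if (is.null(node_names))
    node_names <- sprintf("node_%02d", seq_len(disconnectome$n_nodes))
  dimnames(m) <- list(node_names, node_names)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a disconnectome TSV back into a matrix
#' @param path File path.
#' @return Symmetric numeric matrix with node-name dimnames.
#' @export
read_disconnectome_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' Write a weight map (feature id, weight, z, null moments) as TSV
#' @param wm A `weight_map`.
#' @param path Output path.
#' @export
write_weight_map_tsv <- function(wm, path) {
  df <- data.frame(feature_id = wm$feature_ids, weight = wm$weights)
  if (!is.null(wm$z_scores)) {
    df$z <- wm$z_scores
    df$null_mean <- wm$null_mean
    df$null_sd <- wm$null_sd
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the cluster table (atlas-labeled voxel clusters) as TSV
#'
#' Center-of-mass coordinates are exported 0-based.
#' @param labels Data frame from [label_clusters()].
#' @param path Output path.
#' @export
write_cluster_table_tsv <- function(labels, path) {
  out <- labels
  for (col in c("com_x", "com_y", "com_z"))
    if (col %in% names(out)) out[[col]] <- out[[col]] - 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write significant edges / subgraph membership as TSV
#' @param edges An `edge_set`.
#' @param subgraph Optional `subgraph`; adds an `in_subgraph` column.
#' @param path Output path.
#' @export
write_edges_tsv <- function(edges, path, subgraph = NULL) {
  out <- as.data.frame(edges)
  if (!is.null(subgraph)) {
    key <- paste(out$node_i, out$node_j)
    skey <- paste(subgraph$edges$node_i, subgraph$edges$node_j)
    out$in_subgraph <- key %in% skey
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Expected fields: `analysis` ("tool_use" or "grip"), optional paths
#' (`lesion_dir`, `behavior`, `out_dir`), `seed`, and an `svr` block with
#' any of the [svr_config()] fields.
#'
#' @param path YAML file path.
#' @return List with a validated `analysis` field and an `svr_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$analysis) || !cfg$analysis %in% c("tool_use", "grip"))
    stop("config must set analysis: tool_use or grip")
  svr_args <- cfg$svr
  if (is.null(svr_args)) svr_args <- list()
  if (!is.null(cfg$seed)) svr_args$seed <- cfg$seed
  cfg$svr <- do.call(svr_config, svr_args)
  cfg
}

#' Write a provenance manifest for an artifact bundle
#' @param manifest Named list (config, seeds, file checksums...).
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
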