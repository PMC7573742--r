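# End-to-end orchestration of the two study analyses (tool-use gesturing;
# right-hand grip strength): behavior preparation -> SVR-VLSM -> localizer
# region extraction -> disconnectome -> three-factor nuisance regression ->
# SVR-CLSM -> maximally disconnected subgraph -> optional seed analysis.

#' Run the full lesion-symptom mapping pipeline
#'
#' For `analysis = "tool_use"` the voxel-level dependent measure is the
#' tool-use score residualized on the imitation score; the edge-level
#' measure additionally residualizes out total lesion volume. For
#' `analysis = "grip"` the right-hand grip score is residualized on the
#' left-hand score (plus lesion volume for the edge analysis) over the
#' grip-complete subjects. Edge disconnection is residualized on cumulative
#' disconnection of the regions implicated by the voxel analysis, total
#' lesion volume, and months post-stroke, before entering the edge SVR.
#'
#' When `lesions` is `NULL`, only the behavior-level artifacts
#' (correlations and residual scores) are produced and the imaging stages
#' are skipped with a notice — the partial-input contract for cohorts whose
#' imaging is unavailable.
#'
#' @param behavior A `behavior_table`.
#' @param lesions List of `lesion_mask` aligned to `behavior` rows, or
#'   `NULL`.
#' @param parcellation,atlas Anatomy for the imaging stages.
#' @param analysis `"tool_use"` or `"grip"`.
#' @param config An `svr_config` (applies to both SVR stages).
#' @param min_lesion_frac Coverage fraction for voxels and edges.
#' @param z_thresh Significance threshold for both stages.
#' @param min_cluster Cluster extent; `NULL` = desk-scale rule.
#' @param seed_node Optional node id for the post-hoc seed analysis.
#' @param subgraph_solver Passed to [max_disconnected_subgraph()].
#' @param out_dir Optional directory; when given, all artifacts are written
#'   as TSV plus a JSON manifest carrying the configuration, seeds and file
#'   checksums.
#' @return List bundle with the stage outputs that were run.
#' @export
run_full_pipeline <- function(behavior, lesions = NULL, parcellation = NULL,
                              atlas = NULL,
                              analysis = c("tool_use", "grip"),
                              config = svr_config(),
                              min_lesion_frac = 0.10, z_thresh = -1.65,
                              min_cluster = NULL, seed_node = NULL,
                              subgraph_solver = "auto", out_dir = NULL) {
  analysis <- match.arg(analysis)
  behavior <- validate_behavior_table(behavior)
  bundle <- list(analysis = analysis, config = config)

  if (analysis == "tool_use") {
    keep <- rep(TRUE, nrow(behavior))
    y1 <- behavior$gts_hp
    x1 <- cbind(imi_hp = behavior$imi_hp)
  } else {
    keep <- stats::complete.cases(behavior$lh_grip, behavior$rh_grip)
    y1 <- behavior$rh_grip[keep]
    x1 <- cbind(lh_grip = behavior$lh_grip[keep])
  }
  beh <- behavior[keep, , drop = FALSE]
  ids <- beh$subject_id
  bundle$subjects <- ids
  bundle$behavior_correlation <- pearson_r(y1, x1[, 1L])
  target_vlsm <- residualize(y1, x1, subject_ids = ids)
  target_clsm <- residualize(y1, cbind(x1, lesion_volume = beh$lesion_volume),
                             subject_ids = ids)
  bundle$target_vlsm <- target_vlsm
  bundle$target_clsm <- target_clsm

  if (is.null(lesions)) {
    bundle$skipped <- paste("imaging stages skipped: no lesion data;",
                            "behavior-only artifacts produced")
    message(bundle$skipped)
  } else {
    stopifnot(!is.null(parcellation), !is.null(atlas))
    lesions <- lesions[keep]
    vlsm <- run_vlsm(lesions, target_vlsm, config,
                     min_lesion_frac = min_lesion_frac, z_thresh = z_thresh,
                     min_cluster = min_cluster)
    bundle$vlsm <- vlsm
    cluster_labels <- label_clusters(vlsm, parcellation)
    bundle$cluster_labels <- cluster_labels
    region_nodes <- sort(unique(cluster_labels$node_id))

    edge_matrix <- batch_disconnectomes(lesions, atlas)
    bundle$edge_matrix <- edge_matrix
    included <- edge_coverage_mask(edge_matrix, length(lesions),
                                   min_fraction = min_lesion_frac)
    covs <- cbind(lesion_volume = beh$lesion_volume,
                  months_post = beh$months_post)
    if (length(region_nodes)) {
      covs <- cbind(
        region_disconnection = cumulative_region_disconnection_matrix(
          edge_matrix, region_nodes, n_nodes(parcellation)),
        covs)
    }
    residual_edges <- nuisance_residualize_edges(edge_matrix, covs)
    bundle$residual_edges <- residual_edges
    zmat <- run_clsm(residual_edges, target_clsm, config,
                     n_nodes = n_nodes(parcellation),
                     included_edges = included, z_thresh = z_thresh)
    bundle$zmatrix <- zmat
    sig <- significant_edges(zmat, z_thresh)
    bundle$significant_edges <- sig
    bundle$subgraph <- max_disconnected_subgraph(sig, subgraph_solver)
    bundle$node_counts <- node_disconnection_count(sig, n_nodes(parcellation))

    if (!is.null(seed_node)) {
      bundle$seed_report <- build_seed_report(
        residual_edges[, included, drop = FALSE], seed_node, target_clsm,
        parcellation, vlsm$overlap,
        n_permutations = max(100L, config$n_permutations %/% 10L),
        seed = config$seed)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    wr <- function(fn, name) {
      p <- file.path(out_dir, name)
      fn(p)
      files[[length(files) + 1L]] <<- p
      p
    }
    wr(function(p) utils::write.table(
      data.frame(subject_id = ids, residual_vlsm = target_vlsm$values,
                 residual_clsm = target_clsm$values),
      p, sep = "\t", quote = FALSE, row.names = FALSE),
      "residual_scores.tsv")
    if (!is.null(bundle$vlsm)) {
      wr(function(p) write_cluster_table_tsv(bundle$cluster_labels, p),
         "cluster_table.tsv")
      wr(function(p) write_weight_map_tsv(bundle$vlsm$weight_map, p),
         "vlsm_weight_map.tsv")
      wr(function(p) write_edges_tsv(bundle$significant_edges, p,
                                     bundle$subgraph),
         "significant_edges.tsv")
      wr(function(p) utils::write.table(
        data.frame(node_id = seq_along(bundle$node_counts),
                   count = as.integer(bundle$node_counts)),
        p, sep = "\t", quote = FALSE, row.names = FALSE),
        "node_disconnection_counts.tsv")
      if (!is.null(bundle$seed_report))
        wr(function(p) utils::write.table(as.data.frame(bundle$seed_report),
                                          p, sep = "\t", quote = FALSE,
                                          row.names = FALSE),
           "seed_report.tsv")
    }
    manifest <- list(
      package = "disconlsm",
      version = as.character(utils::packageVersion("disconlsm")),
      analysis = analysis,
      n_subjects = length(ids),
      seed = config$seed,
      config = unclass(config),
      coordinate_convention = "0-based, dimension-ordered",
      skipped = bundle$skipped,
      files = lapply(stats::setNames(files, basename(unlist(files))),
                     function(p) unname(tools::md5sum(p)))
    )
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    bundle$out_dir <- out_dir
  }
  bundle
}
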