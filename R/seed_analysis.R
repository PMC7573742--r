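# Post-hoc seed-node disconnection analysis: three sequential criteria
# filtering remote nodes whose residual disconnection from a chosen seed
# predicts behavior. (1) the remote node lies essentially outside the
# lesion territory; (2) the seed-remote disconnection correlates negatively
# with behavior at one-tailed P < .05; (3) the correlation is at least
# ~2 SD below a Monte Carlo permutation null (z < -1.96).

#' Fraction of a node's voxels inside the lesion territory
#'
#' Criterion 1 screens remote nodes for weak-signal contamination: the
#' default reading is the fraction of node voxels lesioned in at least one
#' subject; `weighted = TRUE` instead averages the per-voxel subject counts
#' relative to cohort size.
#'
#' @param node_voxel_set Linear voxel indices of the node (non-empty).
#' @param overlap_map Integer volume of per-voxel lesion counts.
#' @param weighted Use the count-weighted variant.
#' @param n_subjects Cohort size (required when `weighted`).
#' @return Fraction in [0, 1].
#' @export
node_lesion_overlap_fraction <- function(node_voxel_set, overlap_map,
                                         weighted = FALSE,
                                         n_subjects = NULL) {
  if (!length(node_voxel_set)) stop("empty node voxel set")
  if (weighted) {
    stopifnot(!is.null(n_subjects))
    mean(overlap_map[node_voxel_set]) / n_subjects
  } else {
    mean(overlap_map[node_voxel_set] >= 1L)
  }
}

seed_edge_columns <- function(edge_colnames, seed_node) {
  parts <- strsplit(edge_colnames, "|", fixed = TRUE)
  i <- as.integer(vapply(parts, `[[`, "", 1L))
  j <- as.integer(vapply(parts, `[[`, "", 2L))
  hit <- i == seed_node | j == seed_node
  data.frame(col = which(hit), remote = ifelse(i[hit] == seed_node,
                                               j[hit], i[hit]))
}

#' Screen seed-node edges by behavioral correlation
#'
#' Criterion 2: Pearson r between each seed-remote residual disconnection
#' column and the behavioral residual, with a one-tailed p for the negative
#' direction (more disconnection, worse behavior). Zero-variance columns
#' are excluded with a flag.
#'
#' @param residual_edges Subjects x edges matrix with "i|j" column names
#'   (include only analyzable edges, e.g. after coverage masking).
#' @param seed_node Seed node id.
#' @param target `residual_scores` or numeric vector.
#' @param alpha One-tailed significance level (default 0.05).
#' @return Data frame: `remote_node`, `r`, `one_tailed_p`, `pass`,
#'   `excluded`.
#' @export
seed_edge_screen <- function(residual_edges, seed_node, target,
                             alpha = 0.05) {
  y <- as_target(target)
  cols <- seed_edge_columns(colnames(residual_edges), seed_node)
  if (!nrow(cols)) stop("seed node ", seed_node, " has no included edges")
  n <- length(y)
  out <- lapply(seq_len(nrow(cols)), function(k) {
    x <- residual_edges[, cols$col[k]]
    if (stats::sd(x) == 0)
      return(data.frame(remote_node = cols$remote[k], r = NA_real_,
                        one_tailed_p = NA_real_, pass = FALSE,
                        excluded = TRUE))
    r <- stats::cor(x, y)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- stats::pt(tstat, df = n - 2)  # lower tail: negative association
    data.frame(remote_node = cols$remote[k], r = r, one_tailed_p = p,
               pass = p < alpha, excluded = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$remote_node), , drop = FALSE]
}

#' Permutation z-scores for seed-node edge correlations
#'
#' Criterion 3: for each seed-remote edge, the null distribution of the
#' behavior-disconnection correlation under seeded shuffling of the
#' behavioral vector; `z = (r_true - mean_null) / sd_null`.
#'
#' @inheritParams seed_edge_screen
#' @param n_permutations Number of shuffles (>= 100; study default 10000).
#' @param seed Integer seed.
#' @param z_crit Pass threshold (strict `z < z_crit`, default -1.96).
#' @return Data frame: `remote_node`, `r`, `z`, `pass`, `degenerate`.
#' @export
seed_permutation_z <- function(residual_edges, seed_node, target,
                               n_permutations = 10000L, seed = 1L,
                               z_crit = -1.96) {
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  y <- as_target(target)
  cols <- seed_edge_columns(colnames(residual_edges), seed_node)
  if (!nrow(cols)) stop("seed node ", seed_node, " has no included edges")
  M <- residual_edges[, cols$col, drop = FALSE]
  ok <- apply(M, 2L, stats::sd) > 0
  r_true <- rep(NA_real_, ncol(M))
  r_true[ok] <- drop(stats::cor(y, M[, ok, drop = FALSE]))
  null_r <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      yp <- y[sample.int(length(y))]
      r <- rep(NA_real_, ncol(M))
      r[ok] <- drop(stats::cor(yp, M[, ok, drop = FALSE]))
      r
    }, numeric(ncol(M)))
  })
  mu <- rowMeans(null_r)
  sdv <- apply(null_r, 1L, stats::sd)
  zs <- zscore_weights(ifelse(is.na(r_true), 0, r_true),
                       ifelse(is.na(mu), 0, mu),
                       ifelse(is.na(sdv), 0, sdv))
  z <- ifelse(ok, zs$z, NA_real_)
  out <- data.frame(remote_node = cols$remote, r = r_true, z = z,
                    pass = !is.na(z) & z < z_crit,
                    degenerate = !ok | zs$degenerate)
  out[order(out$remote_node), , drop = FALSE]
}

#' Build the full seed-node disconnection report
#'
#' Joins the three criteria into one diagnostic table; the final pass set
#' is their pure conjunction, so criterion order never changes the result.
#' All candidate remote nodes are retained with their per-criterion flags.
#'
#' @inheritParams seed_edge_screen
#' @param parcellation A `parcellation` (for node voxel sets and names).
#' @param overlap_map Integer lesion-overlap volume (criterion 1).
#' @param overlap_max Criterion-1 bound on the overlap fraction (default
#'   0.01, i.e. less than 1% of node voxels inside the lesion territory).
#' @param n_permutations,seed Permutation settings for criterion 3.
#' @param z_crit Criterion-3 threshold (default -1.96).
#' @return Data frame of class `seed_report`, sorted by remote node id,
#'   with columns `remote_node`, `node_name`, `lesion_overlap_fraction`,
#'   `r`, `one_tailed_p`, `z`, `pass_overlap`, `pass_correlation`,
#'   `pass_permutation`, `pass_all`; the seed node id is attached as the
#'   `seed_node` attribute.
#' @export
build_seed_report <- function(residual_edges, seed_node, target,
                              parcellation, overlap_map,
                              alpha = 0.05, overlap_max = 0.01,
                              n_permutations = 1000L, seed = 1L,
                              z_crit = -1.96) {
  screen <- seed_edge_screen(residual_edges, seed_node, target, alpha)
  perm <- seed_permutation_z(residual_edges, seed_node, target,
                             n_permutations, seed, z_crit)
  stopifnot(identical(screen$remote_node, perm$remote_node))
  ovl <- vapply(screen$remote_node, function(nd) {
    node_lesion_overlap_fraction(node_voxels(parcellation, nd), overlap_map)
  }, numeric(1))
  rep_df <- data.frame(
    remote_node = screen$remote_node,
    node_name = parcellation$node_names[screen$remote_node],
    lesion_overlap_fraction = ovl,
    r = screen$r,
    one_tailed_p = screen$one_tailed_p,
    z = perm$z,
    pass_overlap = ovl < overlap_max,
    pass_correlation = screen$pass,
    pass_permutation = perm$pass,
    stringsAsFactors = FALSE
  )
  rep_df$pass_all <- rep_df$pass_overlap & rep_df$pass_correlation &
    rep_df$pass_permutation
  rep_df <- rep_df[order(rep_df$remote_node), , drop = FALSE]
  attr(rep_df, "seed_node") <- seed_node
  class(rep_df) <- c("seed_report", "data.frame")
  rep_df
}
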