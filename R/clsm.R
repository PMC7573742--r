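# Edge-level SVR-CLSM: three-factor nuisance regression of edge
# disconnection, permutation z-matrix, significant-edge extraction,
# maximally disconnected subgraph and node-level disconnection counts.

#' Residualize edge disconnection on nuisance covariates
#'
#' Per-edge ordinary least-squares residuals (intercept included) after
#' regressing each edge's disconnection values on the nuisance design —
#' in the study pipeline: cumulative disconnection of the voxel-analysis
#' regions, total lesion volume, and months post-stroke.
#'
#' @param edge_matrix Subjects x edges numeric matrix.
#' @param covariates Numeric vector, matrix or data frame aligned to
#'   subjects.
#' @return Residual matrix of the same shape; columns orthogonal to every
#'   covariate.
#' @export
nuisance_residualize_edges <- function(edge_matrix, covariates) {
  edge_matrix <- as.matrix(edge_matrix)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == nrow(edge_matrix))
  if (anyNA(X)) stop("missing values in covariates")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  zero_var <- apply(X, 2L, stats::sd) == 0
  if (any(zero_var))
    stop("zero-variance covariate(s): ",
         paste(colnames(X)[zero_var], collapse = ", "))
  design <- cbind(`(intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    # name the collinear pair for the error message
    cc <- stats::cor(X)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1L, ]
    stop("collinear covariates: ", colnames(X)[worst[1L]], " and ",
         colnames(X)[worst[2L]])
  }
  res <- qr.resid(qrd, edge_matrix)
  dimnames(res) <- dimnames(edge_matrix)
  res
}

#' Run the SVR-CLSM analysis over residualized edges
#'
#' Delegates to the shared permutation machinery over the included edge
#' columns, then devectorizes the z-scores into a symmetric node x node
#' matrix (NA where an edge was not included).
#'
#' @param residual_edges Subjects x edges matrix (typically the output of
#'   [nuisance_residualize_edges()]), with "i|j" column names.
#' @param target `residual_scores` or numeric vector.
#' @param config An `svr_config` (Gaussian kernel, scale 1 by default).
#' @param n_nodes Number of parcellation nodes.
#' @param included_edges Logical vector over columns (default: all);
#'   usually an [edge_coverage_mask()] computed on the raw disconnection
#'   matrix.
#' @param z_thresh Recorded threshold (default -1.65).
#' @return Object of class `zmatrix`: `n_nodes`, `z` (symmetric, NA off
#'   included edges), `included_edges` (named logical), `threshold`,
#'   `weight_map`.
#' @export
run_clsm <- function(residual_edges, target, config = svr_config(), n_nodes,
                     included_edges = NULL, z_thresh = -1.65) {
  residual_edges <- as.matrix(residual_edges)
  if (is.null(colnames(residual_edges)))
    stop("residual_edges needs 'i|j' column names")
  if (is.null(included_edges))
    included_edges <- rep(TRUE, ncol(residual_edges))
  if (!any(included_edges)) stop("no included edges")
  feats <- residual_edges[, included_edges, drop = FALSE]
  wm <- permutation_zscores(feats, target, config)
  zvec <- wm$z_scores
  names(zvec) <- colnames(feats)
  zmat <- devectorize_edges(zvec, n_nodes)
  inc <- stats::setNames(as.logical(included_edges), colnames(residual_edges))
  structure(list(
    n_nodes = n_nodes, z = zmat, included_edges = inc,
    threshold = z_thresh, weight_map = wm
  ), class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat("zmatrix:", x$n_nodes, "nodes,", sum(x$included_edges),
      "included edges, threshold z <", x$threshold, "\n")
  invisible(x)
}

#' Edges surviving the permutation threshold
#'
#' @param zmat A `zmatrix`.
#' @param thresh Threshold (strict `z < thresh`), default -1.65.
#' @return Data frame (class `edge_set`) with one row per undirected edge:
#'   `node_i`, `node_j` (i < j), `z`, `weight` (= |z|).
#' @export
significant_edges <- function(zmat, thresh = -1.65) {
  ep <- edge_pairs(zmat$n_nodes)
  zv <- zmat$z[ep]
  keep <- !is.na(zv) & zv < thresh
  out <- data.frame(node_i = ep[keep, 1L], node_j = ep[keep, 2L],
                    z = zv[keep], weight = abs(zv[keep]))
  class(out) <- c("edge_set", "data.frame")
  out
}

#' Weighted edge set constructor
#' @param node_i,node_j Node ids (i < j enforced by sorting).
#' @param weight Positive weights.
#' @param z Optional signed z values (default `-weight`).
#' @return An `edge_set` data frame.
#' @export
edge_set <- function(node_i, node_j, weight, z = -weight) {
  stopifnot(length(node_i) == length(node_j), length(weight) == length(node_i))
  out <- data.frame(node_i = pmin(node_i, node_j),
                    node_j = pmax(node_i, node_j), z = z, weight = weight)
  class(out) <- c("edge_set", "data.frame")
  out
}

#' Maximally disconnected subgraph
#'
#' Among connected subgraphs of the significant-edge graph, returns one
#' maximizing the total edge weight (sum of |z|). Because every surviving
#' edge has strictly positive weight, adding an edge never decreases the
#' objective, so the exact optimum is the connected component with the
#' greatest total weight; the `"exact"` solver evaluates every component.
#' The `"greedy"` solver grows from the single heaviest edge, repeatedly
#' absorbing the heaviest edge incident to the current node set — it can
#' settle for the heaviest edge's component rather than the heaviest
#' component. `"auto"` uses the exact solver up to 15 nodes, greedy beyond.
#'
#' @param edges An `edge_set` (e.g. from [significant_edges()]).
#' @param solver `"auto"`, `"exact"` or `"greedy"`.
#' @return Object of class `subgraph`: `nodes`, `edges` (rows of the
#'   input), `total_weight`, `node_degree_counts` (named by node id), and
#'   a `solver_used` field recording the algorithm.
#' @export
max_disconnected_subgraph <- function(edges, solver = c("auto", "exact",
                                                        "greedy")) {
  solver <- match.arg(solver)
  if (nrow(edges) == 0L) {
    return(structure(list(nodes = integer(0),
                          edges = edges, total_weight = 0,
                          node_degree_counts = integer(0),
                          solver_used = solver),
                     class = "subgraph"))
  }
  if (any(edges$weight <= 0)) stop("edge weights must be > 0")
  nodes_all <- sort(unique(c(edges$node_i, edges$node_j)))
  if (solver == "auto")
    solver <- if (length(nodes_all) <= 15L) "exact" else "greedy"
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$node_i),
               to = as.character(edges$node_j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes_all))
  )
  if (solver == "exact") {
    comp <- igraph::components(g)
    member_of <- comp$membership[as.character(edges$node_i)]
    totals <- tapply(edges$weight, member_of, sum)
    best <- as.integer(names(totals)[which.max(totals)])
    keep <- member_of == best
  } else {
    start <- which.max(edges$weight)
    in_nodes <- c(edges$node_i[start], edges$node_j[start])
    keep <- logical(nrow(edges))
    keep[start] <- TRUE
    repeat {
      cand <- which(!keep & (edges$node_i %in% in_nodes |
                               edges$node_j %in% in_nodes))
      if (!length(cand)) break
      nxt <- cand[which.max(edges$weight[cand])]
      keep[nxt] <- TRUE
      in_nodes <- unique(c(in_nodes, edges$node_i[nxt], edges$node_j[nxt]))
    }
  }
  sub <- edges[keep, , drop = FALSE]
  nodes <- sort(unique(c(sub$node_i, sub$node_j)))
  deg <- table(factor(c(sub$node_i, sub$node_j), levels = nodes))
  structure(list(
    nodes = nodes, edges = sub, total_weight = sum(sub$weight),
    node_degree_counts = stats::setNames(as.integer(deg), names(deg)),
    solver_used = solver
  ), class = "subgraph")
}

#' @export
print.subgraph <- function(x, ...) {
  cat("subgraph (", x$solver_used, "): ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges, total |z| = ", round(x$total_weight, 3),
      "\n", sep = "")
  invisible(x)
}

#' Node-level disconnection counts
#'
#' Number of surviving edges incident to each node — the cumulative
#' disconnection-count map aggregated from the significant edge set.
#'
#' @param edges An `edge_set`.
#' @param n_nodes Number of nodes (default: max node id present).
#' @return Integer vector of length `n_nodes` named by node id; sums to
#'   twice the edge count (handshake identity).
#' @export
node_disconnection_count <- function(edges,
                                     n_nodes = if (nrow(edges)) max(edges$node_i, edges$node_j) else 0L) {
  counts <- integer(n_nodes)
  names(counts) <- as.character(seq_len(n_nodes))
  if (nrow(edges)) {
    tb <- table(factor(c(edges$node_i, edges$node_j),
                       levels = seq_len(n_nodes)))
    counts <- stats::setNames(as.integer(tb), names(counts))
  }
  counts
}
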