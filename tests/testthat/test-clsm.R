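test_that("edge nuisance residualization matches closed-form OLS", {
  # 4-subject toy with one covariate, residuals from the hand formula
  x <- c(1, 2, 3, 4)
  e <- c(2, 3, 5, 9)
  em <- cbind(`1|2` = e)
  fit <- stats::lm(e ~ x)
  res <- nuisance_residualize_edges(em, cbind(x = x))
  expect_equal(unname(res[, 1]), unname(stats::resid(fit)), tolerance = 1e-9)
  # edge exactly linear in the covariate residualizes to ~0
  res2 <- nuisance_residualize_edges(cbind(`1|2` = 2 * x + 1), cbind(x = x))
  expect_lt(max(abs(res2)), 1e-10)
  # orthogonality to every covariate
  set.seed(41)
  EM <- matrix(runif(20 * 6), 20, 6)
  CV <- cbind(vol = rlnorm(20), months = runif(20, 3, 100))
  R <- nuisance_residualize_edges(EM, CV)
  expect_lt(max(abs(crossprod(scale(CV, scale = FALSE), R))), 1e-8)
  # degenerate designs are rejected with names
  expect_error(nuisance_residualize_edges(EM, cbind(a = rep(1, 20))),
               "zero-variance")
  expect_error(nuisance_residualize_edges(EM, cbind(a = CV[, 1],
                                                    b = 2 * CV[, 1])),
               "collinear")
})

test_that("run_clsm devectorizes z-scores symmetrically over included edges", {
  set.seed(42)
  n <- 20
  em <- matrix(runif(n * 6), n,
               dimnames = list(NULL, c("1|2", "1|3", "1|4", "2|3", "2|4",
                                       "3|4")))
  y <- rnorm(n)
  inc <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  zm <- run_clsm(em, y, svr_config(n_permutations = 100, seed = 6),
                 n_nodes = 4L, included_edges = inc)
  expect_s3_class(zm, "zmatrix")
  expect_true(is.na(zm$z[1, 3]))
  expect_false(is.na(zm$z[1, 2]))
  expect_equal(zm$z[2, 1], zm$z[1, 2])
  expect_equal(sum(!is.na(zm$z[upper.tri(zm$z)])), 4L)
  # single included edge -> exactly one defined off-diagonal pair
  zm1 <- run_clsm(em, y, svr_config(n_permutations = 100, seed = 6),
                  n_nodes = 4L,
                  included_edges = c(TRUE, rep(FALSE, 5)))
  expect_equal(sum(!is.na(zm1$z[upper.tri(zm1$z)])), 1L)
})

test_that("significant_edges applies the strict one-tailed boundary once per edge", {
  z <- devectorize_edges(c(`1|2` = -2.0, `1|3` = -1.65, `2|3` = -1.0), 3L)
  zm <- structure(list(n_nodes = 3L, z = z, included_edges = NULL,
                       threshold = -1.65), class = "zmatrix")
  se <- significant_edges(zm)
  expect_equal(nrow(se), 1L)
  expect_equal(se$node_i, 1L)
  expect_equal(se$node_j, 2L)
  expect_equal(se$weight, 2.0)
  zall <- structure(list(n_nodes = 3L,
                         z = devectorize_edges(rep(0, 3), 3L)),
                    class = "zmatrix")
  expect_equal(nrow(significant_edges(zall)), 0L)
})

test_that("subgraph extraction picks the heaviest connected component", {
  # single edge
  s1 <- max_disconnected_subgraph(edge_set(1L, 2L, weight = 2))
  expect_equal(s1$total_weight, 2)
  expect_equal(s1$nodes, c(1L, 2L))
  # component {A,B,C} with weights 2+2 beats component {D,E} with weight 3
  es <- edge_set(c(1L, 2L, 4L), c(2L, 3L, 5L), weight = c(2, 2, 3))
  ex <- max_disconnected_subgraph(es, "exact")
  expect_equal(ex$total_weight, 4)
  expect_equal(ex$nodes, 1:3)
  # greedy starts at the heaviest edge and stays in its component
  gr <- max_disconnected_subgraph(es, "greedy")
  expect_equal(gr$total_weight, 3)
  # empty input -> empty subgraph
  e0 <- max_disconnected_subgraph(es[0, ])
  expect_equal(e0$total_weight, 0)
  expect_length(e0$nodes, 0L)
  expect_error(max_disconnected_subgraph(edge_set(1L, 2L, weight = 0)),
               "> 0")
})

test_that("exact solver equals exhaustive enumeration on small random graphs", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    ep <- edge_pairs(n)
    keep <- runif(nrow(ep)) < 0.5
    if (!any(keep)) next
    es <- edge_set(ep[keep, 1L], ep[keep, 2L],
                   weight = runif(sum(keep), 0.1, 3))
    ex <- max_disconnected_subgraph(es, "exact")
    oracle <- brute_max_connected_subgraph(es)
    expect_equal(ex$total_weight, oracle$total, tolerance = 1e-12)
  }
})

test_that("greedy agrees with exact on most dense 12-node graphs", {
  set.seed(44)
  agree <- 0L
  for (i in 1:50) {
    ep <- edge_pairs(12L)
    keep <- runif(nrow(ep)) < 0.25
    if (!any(keep)) keep[1] <- TRUE
    es <- edge_set(ep[keep, 1L], ep[keep, 2L],
                   weight = runif(sum(keep), 0.1, 3))
    ex <- max_disconnected_subgraph(es, "exact")
    gr <- max_disconnected_subgraph(es, "greedy")
    if (isTRUE(all.equal(ex$total_weight, gr$total_weight))) agree <- agree + 1L
  }
  expect_gte(agree, 45L)
})

test_that("node counts satisfy the handshake identity", {
  es <- edge_set(c(1L, 1L, 1L, 1L), c(2L, 3L, 4L, 5L), weight = rep(1, 4))
  counts <- node_disconnection_count(es, 5L)
  expect_equal(unname(counts), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(sum(counts), 2L * nrow(es))
  expect_true(all(node_disconnection_count(es[0, ], 5L) == 0L))
  set.seed(45)
  ep <- edge_pairs(9L)
  keep <- runif(nrow(ep)) < 0.4
  es2 <- edge_set(ep[keep, 1L], ep[keep, 2L], weight = runif(sum(keep)))
  expect_equal(sum(node_disconnection_count(es2, 9L)), 2L * nrow(es2))
})

test_that("a hub with planted incident-edge effects tops the disconnection counts", {
  an <- tiny_anatomy()
  parc <- an$parcellation
  hub <- default_planted_model(parc, an$territory)$target_edge_nodes[1L]
  others <- setdiff(seq_len(n_nodes(parc)), hub)
  hub_edges <- lapply(others, function(o) sort(c(hub, o)))
  model <- planted_model(target_edges = hub_edges,
                         effect_sizes = c(target = 0, edge = 0.8,
                                          shared = 0, motor = 0),
                         noise_sd = 0.01)
  hits <- 0L
  for (s in 1:5) {
    cohort <- generate_cohort(parc, an$atlas, model, n_subjects = 40L,
                              seed = 900L + s, territory = an$territory)
    beh <- cohort$behavior
    target <- residualize(beh$gts_hp,
                          cbind(imi_hp = beh$imi_hp,
                                lesion_volume = beh$lesion_volume))
    edges <- batch_disconnectomes(cohort$lesions, an$atlas)
    included <- edge_coverage_mask(edges, 40L)
    resid <- nuisance_residualize_edges(
      edges, cbind(lesion_volume = beh$lesion_volume,
                   months_post = beh$months_post))
    zm <- run_clsm(resid, target, svr_config(n_permutations = 100,
                                             seed = 900L + s),
                   n_nodes = n_nodes(parc), included_edges = included)
    counts <- node_disconnection_count(significant_edges(zm),
                                       n_nodes(parc))
    if (max(counts) > 0 && which.max(counts) == hub) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("subgraph degree counts are consistent with its edge set", {
  set.seed(46)
  ep <- edge_pairs(8L)
  keep <- runif(nrow(ep)) < 0.35
  es <- edge_set(ep[keep, 1L], ep[keep, 2L], weight = runif(sum(keep), 0.1, 2))
  sg <- max_disconnected_subgraph(es, "exact")
  expect_true(all(sg$edges$node_i %in% sg$nodes))
  expect_true(all(sg$edges$node_j %in% sg$nodes))
  expect_equal(sum(sg$node_degree_counts), 2L * nrow(sg$edges))
  expect_equal(sg$total_weight, sum(sg$edges$weight))
})
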