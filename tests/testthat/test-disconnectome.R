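grid8 <- c(8L, 8L, 8L)

toy_atlas_3node <- function() {
  # single reference path per pair with hand-set probabilities
  manual_atlas(3L, grid8, list(
    "1|2" = list(list(vox = c(10L, 20L, 30L), p = c(0.5, 0.3, 0.2))),
    "1|3" = list(list(vox = c(40L, 50L), p = c(0.6, 0.4))),
    "2|3" = list(list(vox = c(60L, 70L, 80L, 90L), p = rep(0.25, 4)))
  ))
}

test_that("edge disconnection equals the hand-computed proportion of lost path", {
  atlas <- toy_atlas_3node()
  # lesion hits voxels carrying 0.5 and 0.2 of the 1-2 path -> loss 0.7
  les <- manual_lesion(grid8, c(10L, 30L))
  d <- edge_disconnection(les, atlas)
  expect_equal(d$values[1, 2], 0.7, tolerance = 1e-12)
  expect_equal(d$values[2, 1], 0.7, tolerance = 1e-12)
  expect_equal(d$values[1, 3], 0)
  # empty lesion -> all-zero matrix
  d0 <- edge_disconnection(manual_lesion(grid8, integer(0)), atlas)
  expect_true(all(d0$values == 0))
  # lesion covering every path voxel -> complete disconnection
  d1 <- edge_disconnection(
    manual_lesion(grid8, c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L)),
    atlas)
  expect_true(all(vectorize_edges(d1$values) == 1))
  # matrix invariants
  expect_true(all(diag(d$values) == 0))
  expect_true(all(d$values >= 0 & d$values <= 1))
  expect_equal(d$values, t(d$values), tolerance = 1e-12)
})

test_that("multi-reference pairs average per-reference losses within bounds", {
  atlas <- manual_atlas(2L, grid8, list(
    "1|2" = list(list(vox = c(10L, 20L), p = c(0.5, 0.5)),
                 list(vox = c(10L, 30L), p = c(0.9, 0.1)))
  ))
  les <- manual_lesion(grid8, 10L)
  d <- edge_disconnection(les, atlas)
  losses <- c(0.5, 0.9)
  expect_equal(d$values[1, 2], mean(losses))
  expect_gte(d$values[1, 2], min(losses))
  expect_lte(d$values[1, 2], max(losses))
})

test_that("unconnected pairs are zero and flagged", {
  atlas <- manual_atlas(2L, grid8, list("1|2" = list()))
  d <- edge_disconnection(manual_lesion(grid8, 10L), atlas)
  expect_equal(d$values[1, 2], 0)
  expect_true(d$unconnected[["1|2"]])
})

test_that("batch matrices follow the fixed edge order and duplicate rows", {
  atlas <- toy_atlas_3node()
  l1 <- manual_lesion(grid8, c(10L, 30L), "A")
  l2 <- manual_lesion(grid8, 60L, "B")
  m <- batch_disconnectomes(list(l1, l2, l2), atlas)
  expect_identical(colnames(m), c("1|2", "1|3", "2|3"))
  expect_identical(rownames(m), c("A", "B", "B"))
  expect_equal(m[2, ], m[3, ])
  expect_equal(unname(m[1, "1|2"]), 0.7)
  expect_equal(unname(m[2, "2|3"]), 0.25)
})

test_that("edge vectorization round-trips through the symmetric matrix", {
  set.seed(31)
  for (n in c(3L, 5L, 8L)) {
    m <- matrix(0, n, n)
    ep <- edge_pairs(n)
    vals <- runif(nrow(ep))
    m[ep] <- vals
    m[ep[, 2:1]] <- vals
    v <- vectorize_edges(m)
    expect_equal(unname(v), vals)
    expect_equal(devectorize_edges(v, n), m)
  }
})

test_that("edge coverage uses the strict >0 rule with the floor threshold", {
  em <- matrix(0, 57, 3, dimnames = list(NULL, c("1|2", "1|3", "2|3")))
  em[1:5, 1] <- 0.4          # disconnected in exactly 5 of 57 -> included
  em[1:6, 3] <- 1e-9         # tiny but nonzero in 6 subjects -> included
  keep <- edge_coverage_mask(em, 57)
  expect_true(keep[["1|2"]])
  expect_false(keep[["1|3"]])  # all-zero edge excluded
  expect_true(keep[["2|3"]])
  # raising the per-subject floor drops the near-zero edge
  keep2 <- edge_coverage_mask(em, 57, min_disconnect = 1e-6)
  expect_false(keep2[["2|3"]])
})

test_that("cumulative region disconnection sums unique incident edges", {
  vals <- devectorize_edges(c(`1|2` = 0.5, `1|3` = 0.25, `2|3` = 0.1), 3L,
                            fill = 0)
  d <- structure(list(subject_id = "t", n_nodes = 3L, values = vals,
                      unconnected = NULL), class = "disconnectome")
  expect_equal(cumulative_region_disconnection(d, 1L), 0.75)
  expect_equal(cumulative_region_disconnection(d, 1:3), 0.85)
  zero <- structure(list(subject_id = "z", n_nodes = 3L,
                         values = matrix(0, 3, 3), unconnected = NULL),
                    class = "disconnectome")
  expect_equal(cumulative_region_disconnection(zero, c(1L, 2L)), 0)
  expect_error(cumulative_region_disconnection(d, integer(0)), "empty")
})

test_that("disconnection grows monotonically and adds over disjoint parts", {
  an <- tiny_anatomy()
  atlas <- an$atlas
  dims <- an$parcellation$grid_shape
  set.seed(32)
  for (i in 1:40) {
    small_vox <- generate_lesion(an$parcellation, an$territory,
                                 sample(20:80, 1), seed = 800L + i)
    extra <- voxel_neighbors(which(small_vox$mask == 1L), dims)
    grown_vox <- union(which(small_vox$mask == 1L), extra)
    grown <- manual_lesion(dims, grown_vox)
    d_small <- vectorize_edges(edge_disconnection(small_vox, atlas)$values)
    d_grown <- vectorize_edges(edge_disconnection(grown, atlas)$values)
    expect_true(all(d_grown >= d_small - 1e-12))
  }
  # additivity within one reference path for disjoint lesion parts
  atlas3 <- toy_atlas_3node()
  a <- manual_lesion(grid8, 10L)
  b <- manual_lesion(grid8, 30L)
  ab <- manual_lesion(grid8, c(10L, 30L))
  expect_equal(edge_disconnection(ab, atlas3)$values[1, 2],
               edge_disconnection(a, atlas3)$values[1, 2] +
                 edge_disconnection(b, atlas3)$values[1, 2],
               tolerance = 1e-12)
})
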