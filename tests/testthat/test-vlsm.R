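grid10 <- c(10L, 10L, 10L)

test_that("lesion overlap counts subjects per voxel", {
  empty <- manual_lesion(grid10, integer(0))
  expect_true(all(lesion_overlap_map(list(empty, empty)) == 0L))
  m <- manual_lesion(grid10, c(5L, 6L, 7L))
  expect_equal(lesion_overlap_map(list(m, m)), (m$mask != 0) * 2L,
               ignore_attr = TRUE)
  a <- manual_lesion(grid10, c(1L, 2L))
  b <- manual_lesion(grid10, c(2L, 3L))
  d <- manual_lesion(grid10, c(2L, 9L))
  ov <- lesion_overlap_map(list(a, b, d))
  expect_equal(ov[2L], 3L)
  expect_equal(ov[1L], 1L)
  bad <- manual_lesion(c(9L, 9L, 9L), 1L)
  expect_error(lesion_overlap_map(list(a, bad)), "mismatch")
})

test_that("coverage threshold reproduces the published inclusion counts", {
  expect_equal(coverage_threshold(57), 5L)
  expect_equal(coverage_threshold(41), 4L)
  expect_equal(coverage_threshold(10), 1L)
  ov <- array(0L, grid10)
  ov[3L] <- 5L
  ov[4L] <- 4L
  mask <- coverage_mask(ov, 57)
  expect_true(mask[3L])
  expect_false(mask[4L])
  expect_error(coverage_mask(ov, 57, min_fraction = 0), "min_fraction")
})

test_that("dTLVC scales rows to unit norm and names empty subjects", {
  m <- rbind(S1 = c(1, 1, 1, 1, 0), S2 = c(1, 0, 0, 0, 0))
  s <- dtlvc_scale(m)
  expect_equal(s[1, 1:4], rep(0.5, 4), ignore_attr = TRUE)
  expect_equal(unname(s[2, 1]), 1)
  expect_equal(sqrt(rowSums(s^2)), c(S1 = 1, S2 = 1), tolerance = 1e-9)
  bad <- rbind(S1 = c(1, 0), S2 = c(0, 0))
  expect_error(dtlvc_scale(bad), "S2")
  # explicit volumes: scaling by total volume even on a masked submatrix
  s2 <- dtlvc_scale(rbind(c(1, 1)), volumes = 16)
  expect_equal(s2[1, ], c(0.25, 0.25))
})

test_that("threshold_and_cluster applies strict threshold and extent filter", {
  dims <- c(30L, 30L, 10L)
  z <- array(0, dims)
  mask <- array(TRUE, dims)
  expect_length(threshold_and_cluster(z, mask, -1.65, 1L), 0L)
  # one 600-voxel blob at z=-2 and one 100-voxel blob at z=-3
  big <- as.vector(outer(outer(1:10, (1:10 - 1) * 30, "+"),
                         (1:6 - 1) * 900, "+"))
  small <- as.vector(outer(outer(21:25, (21:25 - 1) * 30, "+"),
                           (7:10 - 1) * 900, "+"))
  z[big] <- -2
  z[small] <- -3
  cl <- threshold_and_cluster(z, mask, -1.65, min_cluster = 500L)
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$size, 600L)
  expect_equal(cl[[1L]]$peak_z, -2)
  expect_setequal(cl[[1L]]$voxels, big)
  # without the extent filter both clusters appear, sorted by size
  cl2 <- threshold_and_cluster(z, mask, -1.65, min_cluster = 1L)
  expect_length(cl2, 2L)
  expect_equal(cl2[[2L]]$size, 100L)
  expect_equal(cl2[[2L]]$peak_z, -3)
  expect_equal(cl2[[2L]]$center_of_mass, c(23, 23, 8.5))
  # boundary: a voxel exactly at the threshold is excluded
  zb <- array(0, dims)
  zb[1L] <- -1.65
  expect_length(threshold_and_cluster(zb, mask, -1.65, 1L), 0L)
})

test_that("raising the extent criterion never increases cluster count", {
  set.seed(21)
  dims <- c(15L, 15L, 15L)
  z <- array(rnorm(prod(dims), -1, 1), dims)
  mask <- array(TRUE, dims)
  counts <- vapply(c(1L, 3L, 5L, 10L, 20L), function(mc)
    length(threshold_and_cluster(z, mask, -1.65, mc)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("cluster labeling splits voxel counts by node without background", {
  parc <- generate_parcellation(c(12L, 12L, 12L), n_nodes = 3L, seed = 2L,
                                fill_fraction = 0.9)
  node3 <- which(parc$labels == 3L)[1:8]
  z <- array(NA_real_, parc$grid_shape)
  mask <- array(FALSE, parc$grid_shape)
  map <- structure(list(grid_shape = parc$grid_shape, in_mask = mask, z = z,
                        clusters = list(list(cluster_id = 1L, voxels = node3,
                                             size = 8L, peak_z = -2.5,
                                             peak_coordinate = c(1L, 1L, 1L),
                                             center_of_mass = c(1, 1, 1)))),
                   class = "voxel_stat_map")
  map$z[node3] <- -2.5
  lab <- label_clusters(map, parc)
  expect_equal(nrow(lab), 1L)
  expect_equal(lab$n_voxels, 8L)
  expect_equal(lab$node_id, 3L)
  # straddling two nodes: per-node counts sum to the cluster size
  n1 <- which(parc$labels == 1L)[1:5]
  n2 <- which(parc$labels == 2L)[1:3]
  map$clusters <- list(list(cluster_id = 1L, voxels = c(n1, n2), size = 8L,
                            peak_z = -3, peak_coordinate = c(1L, 1L, 1L),
                            center_of_mass = c(1, 1, 1)))
  map$z[c(n1, n2)] <- -3
  lab2 <- label_clusters(map, parc)
  expect_equal(nrow(lab2), 2L)
  expect_equal(sum(lab2$n_voxels), 8L)
  expect_equal(lab2$node_id, c(1L, 2L))
  # empty map -> empty table
  map$clusters <- list()
  expect_equal(nrow(label_clusters(map, parc)), 0L)
})

test_that("desk-scale extent rule preserves the full-resolution criterion", {
  expect_equal(scale_min_cluster(c(181L, 217L, 181L)), 500L)
  expect_equal(scale_min_cluster(c(32L, 32L, 32L)), 5L)
})

test_that("component labeling agrees with a brute-force oracle", {
  set.seed(22)
  dims <- c(8L, 8L, 8L)
  for (conn in c(6, 18, 26)) {
    for (i in 1:5) {
      vox <- sample(prod(dims), 25L)
      m <- array(FALSE, dims)
      m[vox] <- TRUE
      got <- label_components(m, conn)
      want <- brute_components(got$index, dims, conn)
      # same partition: equal number of groups and identical co-membership
      expect_equal(got$n, max(want))
      expect_true(all((outer(got$labels, got$labels, "==") ==
                         outer(want, want, "=="))))
    }
  }
})

test_that("dTLVC suppresses the mechanical lesion-volume association", {
  an <- tiny_anatomy()
  model <- default_planted_model(an$parcellation, an$territory, "null")
  frac <- matrix(NA_real_, 4, 2)
  for (s in 1:4) {
    cohort <- generate_cohort(an$parcellation, NULL, model, n_subjects = 30L,
                              seed = 700L + s, territory = an$territory)
    vols <- vapply(cohort$lesions, `[[`, 0L, "volume")
    y <- -scale(vols) + rnorm(30, 0, 0.3)  # behavior driven purely by volume
    ov <- lesion_overlap_map(cohort$lesions)
    midx <- which(coverage_mask(ov, 30L))
    X <- t(vapply(cohort$lesions, function(l) as.numeric(l$mask[midx]),
                  numeric(length(midx))))
    cfg <- svr_config(n_permutations = 100, seed = 700L + s)
    w_raw <- permutation_zscores(X, drop(y), cfg)
    w_dtlvc <- permutation_zscores(dtlvc_scale(X, volumes = vols), drop(y),
                                   cfg)
    frac[s, ] <- c(mean(abs(w_raw$z_scores)), mean(abs(w_dtlvc$z_scores)))
  }
  expect_lt(mean(frac[, 2]), mean(frac[, 1]))
})
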