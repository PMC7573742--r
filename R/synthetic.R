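# Synthetic study generator: toy parcellations, reference path atlases,
# lesion cohorts and planted-effect behavioral scores. Everything is a pure
# function of its arguments including the seed, so calibration and recovery
# studies are exactly reproducible.

#' Generate a toy brain parcellation
#'
#' Nodes are connected voxel blobs grown by seeded random accretion
#' (26-connectivity) from randomly placed centroids, emulating an anatomical
#' parcellation at desk scale. Background (label 0) is allowed.
#'
#' @param grid_shape Integer triple, voxel grid dimensions (default 32^3).
#' @param n_nodes Number of nodes (>= 2), default 12.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param fill_fraction Approximate fraction of the grid covered by nodes.
#' @return Object of class `parcellation`: `grid_shape`, `labels` (3-D
#'   integer array, 0 = background), `node_names`, `node_centroids`
#'   (n x 3 real voxel coordinates, 1-based).
#' @export
generate_parcellation <- function(grid_shape = c(32L, 32L, 32L), n_nodes = 12L,
                                  seed = 1L, fill_fraction = 0.6) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  nv <- prod(grid_shape)
  if (nv < 10L * n_nodes)
    stop("grid too small: need volume >= 10 * n_nodes (", 10L * n_nodes,
         "), got ", nv)
  stopifnot(fill_fraction > 0, fill_fraction <= 1)
  geom <- grid_geometry(grid_shape)
  labels <- with_seed(seed, {
    lab <- array(0L, grid_shape)
    cent <- sample.int(nv, n_nodes)
    lab[cent] <- seq_len(n_nodes)
    target_size <- max(10L, floor(fill_fraction * nv / n_nodes))
    sizes <- rep(1L, n_nodes)
    # per-node frontier stacks with swap-removal; `seen` avoids duplicates
    frontier <- vector("list", n_nodes)
    flen <- integer(n_nodes)
    seen <- lapply(seq_len(n_nodes), function(k) logical(nv))
    for (k in seq_len(n_nodes)) {
      nb <- neighbors26(cent[k], geom)
      frontier[[k]] <- c(nb, integer(length(nb)))
      flen[k] <- length(nb)
      seen[[k]][nb] <- TRUE
    }
    active <- rep(TRUE, n_nodes)
    while (any(active)) {
      for (k in which(active)) {
        if (sizes[k] >= target_size) {
          active[k] <- FALSE
          next
        }
        v <- 0L
        while (flen[k] > 0L) {
          pick <- sample.int(flen[k], 1L)
          cand <- frontier[[k]][pick]
          frontier[[k]][pick] <- frontier[[k]][flen[k]]
          flen[k] <- flen[k] - 1L
          if (lab[cand] == 0L) {
            v <- cand
            break
          }
        }
        if (v == 0L) {
          active[k] <- FALSE
          next
        }
        lab[v] <- k
        sizes[k] <- sizes[k] + 1L
        nb <- neighbors26(v, geom)
        nb <- nb[!seen[[k]][nb] & lab[nb] == 0L]
        if (length(nb)) {
          seen[[k]][nb] <- TRUE
          need <- flen[k] + length(nb)
          if (need > length(frontier[[k]]))
            frontier[[k]] <- c(frontier[[k]],
                               integer(max(need, 2L * length(frontier[[k]]))))
          frontier[[k]][(flen[k] + 1L):need] <- nb
          flen[k] <- need
        }
      }
    }
    lab
  })
  centroids <- t(vapply(seq_len(n_nodes), function(k) {
    colMeans(arrayInd(which(labels == k), grid_shape))
  }, numeric(3)))
  colnames(centroids) <- c("x", "y", "z")
  structure(list(
    grid_shape = grid_shape,
    labels = labels,
    node_names = sprintf("node_%02d", seq_len(n_nodes)),
    node_centroids = centroids
  ), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", length(x$node_names), "nodes on a",
      paste(x$grid_shape, collapse = "x"), "grid;",
      sum(x$labels > 0L), "labeled voxels\n")
  invisible(x)
}

n_nodes <- function(parcellation) length(parcellation$node_names)

#' Voxels of one parcellation node
#' @param parcellation A `parcellation`.
#' @param node Node id (integer) or node name.
#' @return Linear voxel indices.
#' @export
node_voxels <- function(parcellation, node) {
  if (is.character(node)) node <- match(node, parcellation$node_names)
  stopifnot(!is.na(node), node >= 1L, node <= n_nodes(parcellation))
  which(parcellation$labels == node)
}

# Rasterize the straight segment between two (possibly fractional) voxel
# coordinates: sampled at unit steps along the dominant axis and rounded, so
# two centroids 10 voxels apart on an axis visit exactly 11 colinear voxels.
rasterize_segment <- function(a, b) {
  n_steps <- max(abs(round(b) - round(a)))
  if (n_steps == 0) return(matrix(round(a), 1L, 3L))
  t <- seq(0, 1, length.out = n_steps + 1L)
  co <- round(outer(t, b - a) + rep(a, each = length(t)))
  co[!duplicated(co), , drop = FALSE]
}

#' Generate a reference path atlas
#'
#' Emulates shortest-path tractography across a cohort of reference
#' subjects: for every node pair, each reference subject contributes a voxel
#' chain from centroid to centroid (straight segment rasterized, then
#' laterally jittered by rounded Gaussian displacements of sd `jitter_sd`),
#' with visitation probabilities peaked at the chain core and normalized to
#' sum to 1.
#'
#' @param parcellation A `parcellation`.
#' @param n_reference Number of reference subjects (>= 1).
#' @param jitter_sd Gaussian displacement sd in voxels (>= 0); 0 makes all
#'   reference paths for a pair identical.
#' @param seed Integer seed.
#' @return Object of class `ref_path_atlas`: `n_nodes`, `n_reference`,
#'   `grid_shape`, and `paths`, a list keyed "i|j" (i < j) of per-reference
#'   lists with `vox` (linear indices) and `p` (probabilities summing to 1).
#' @export
generate_reference_paths <- function(parcellation, n_reference, jitter_sd = 1,
                                     seed = 1L) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (n_reference < 1L) stop("n_reference must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  dims <- parcellation$grid_shape
  nn <- n_nodes(parcellation)
  ep <- edge_pairs(nn)
  paths <- with_seed(seed, {
    out <- vector("list", nrow(ep))
    for (k in seq_len(nrow(ep))) {
      a <- parcellation$node_centroids[ep[k, 1L], ]
      b <- parcellation$node_centroids[ep[k, 2L], ]
      base <- rasterize_segment(a, b)
      L <- nrow(base)
      # core-peaked weights: triangular profile along the chain
      w <- 1 + pmin(seq_len(L) - 1L, L - seq_len(L))
      refs <- vector("list", n_reference)
      for (r in seq_len(n_reference)) {
        co <- base
        if (jitter_sd > 0 && L > 1L) {
          co <- co + matrix(round(stats::rnorm(3L * L, 0, jitter_sd)), L, 3L)
          co <- pmin(pmax(co, 1L), matrix(dims, L, 3L, byrow = TRUE))
        }
        lin <- coord_to_linear(co, dims)
        p <- vapply(split(w, lin), sum, numeric(1))
        vox <- as.integer(names(p))
        refs[[r]] <- list(vox = vox, p = unname(p / sum(p)))
      }
      out[[k]] <- refs
    }
    names(out) <- edge_id(ep[, 1L], ep[, 2L])
    out
  })
  structure(list(
    n_nodes = nn, n_reference = as.integer(n_reference),
    grid_shape = dims, paths = paths
  ), class = "ref_path_atlas")
}

#' @export
print.ref_path_atlas <- function(x, ...) {
  cat("ref_path_atlas:", x$n_nodes, "nodes,", x$n_reference,
      "reference subjects,", length(x$paths), "node pairs\n")
  invisible(x)
}

new_lesion_mask <- function(mask, subject_id = "synthetic") {
  structure(list(
    subject_id = subject_id,
    mask = mask,
    volume = as.integer(sum(mask != 0))
  ), class = "lesion_mask")
}

#' Construct a lesion mask from a binary volume
#' @param mask 3-D array, nonzero = lesioned.
#' @param subject_id Identifier string.
#' @return Object of class `lesion_mask` with fields `subject_id`, `mask`
#'   (integer 0/1 array) and `volume` (count of lesioned voxels).
#' @export
lesion_mask <- function(mask, subject_id = "subject") {
  stopifnot(length(dim(mask)) == 3L)
  new_lesion_mask(array(as.integer(mask != 0), dim(mask)), subject_id)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("lesion_mask", x$subject_id, "-", x$volume, "voxels on a",
      paste(dim(x$mask), collapse = "x"), "grid\n")
  invisible(x)
}

# Seeded random accretion of a single 26-connected blob inside `territory`
# (logical vector over the grid). Expects RNG state to be set by the caller;
# `geom` (see grid_geometry) is rebuilt when not supplied.
grow_lesion <- function(dims, territory_lgl, target_volume, start = NULL,
                        geom = grid_geometry(dims)) {
  if (is.null(start)) start <- sample_one(which(territory_lgl))
  nv <- length(territory_lgl)
  lesion <- logical(nv)
  in_frontier <- logical(nv)
  lesion[start] <- TRUE
  size <- 1L
  nb <- neighbors26(start, geom)
  nb <- nb[territory_lgl[nb]]
  frontier <- c(nb, integer(length(nb)))
  flen <- length(nb)
  in_frontier[nb] <- TRUE
  while (size < target_volume && flen > 0L) {
    pick <- sample.int(flen, 1L)
    v <- frontier[pick]
    frontier[pick] <- frontier[flen]
    flen <- flen - 1L
    in_frontier[v] <- FALSE
    lesion[v] <- TRUE
    size <- size + 1L
    nb <- neighbors26(v, geom)
    nb <- nb[territory_lgl[nb] & !lesion[nb] & !in_frontier[nb]]
    if (length(nb)) {
      in_frontier[nb] <- TRUE
      need <- flen + length(nb)
      if (need > length(frontier))
        frontier <- c(frontier, integer(max(need, 2L * length(frontier))))
      frontier[(flen + 1L):need] <- nb
      flen <- need
    }
  }
  array(as.integer(lesion), dims)
}

#' Generate one synthetic lesion
#'
#' A single 26-connected blob grown by seeded random accretion from a
#' territory voxel, emulating a single-stroke lesion. The realized volume is
#' `min(target_volume, reachable territory)`.
#'
#' @param parcellation A `parcellation` (defines the grid).
#' @param territory Linear voxel indices the lesion may occupy (non-empty).
#' @param target_volume Desired voxel count (>= 1).
#' @param seed Integer seed.
#' @param start Optional start voxel (linear index inside territory); when
#'   `NULL` the start is drawn uniformly from the territory.
#' @param subject_id Identifier for the output mask.
#' @return A `lesion_mask`.
#' @export
generate_lesion <- function(parcellation, territory, target_volume, seed = 1L,
                            start = NULL, subject_id = "synthetic") {
  stopifnot(inherits(parcellation, "parcellation"))
  if (!length(territory)) stop("territory is empty")
  if (target_volume < 1L) stop("target_volume must be >= 1")
  dims <- parcellation$grid_shape
  terr <- logical(prod(dims))
  terr[territory] <- TRUE
  if (!is.null(start) && !terr[start]) stop("start voxel outside territory")
  mask <- with_seed(seed, grow_lesion(dims, terr, target_volume, start))
  new_lesion_mask(mask, subject_id)
}

#' Left-hemisphere territory of a toy grid
#'
#' The synthetic study restricts lesions to one hemisphere; this returns the
#' low-x half of the grid as linear voxel indices.
#'
#' @param parcellation A `parcellation`.
#' @param fraction Fraction of the x extent belonging to the territory.
#' @return Linear voxel indices.
#' @export
left_hemisphere_territory <- function(parcellation, fraction = 0.5) {
  dims <- parcellation$grid_shape
  xmax <- max(1L, floor(dims[1L] * fraction))
  co <- arrayInd(seq_len(prod(dims)), dims)
  which(co[, 1L] <= xmax)
}

#' Specify the generative model for planted behavioral effects
#'
#' Encodes the generative structure the mapping analyses assume: the primary
#' score falls with fractional lesion load of a target voxel set and with
#' disconnection of target edges; a correlated control score falls with load
#' of a shared voxel set; grip scores fall with load of a motor voxel set on
#' top of a shared per-subject strength factor.
#'
#' @param target_voxel_set Linear voxel indices whose lesion load lowers the
#'   primary score.
#' @param target_edges List of node pairs (length-2 integer vectors) whose
#'   disconnection lowers the primary score.
#' @param shared_voxel_set Voxel set driving the correlated control score.
#' @param motor_voxel_set Voxel set driving right-hand grip strength.
#' @param effect_sizes Named coefficients `target`, `edge`, `shared`,
#'   `motor` (motor is in force units; the others in score units).
#' @param noise_sd Gaussian noise sd on the proportion scores (>= 0).
#' @param baseline Named baselines: `primary`, `control` (proportions) and
#'   `grip` (force units).
#' @param grip_strength_sd Between-subject sd of the shared strength factor.
#' @param grip_noise_sd Trial-level grip noise sd.
#' @return Object of class `planted_model`.
#' @export
planted_model <- function(target_voxel_set = integer(0),
                          target_edges = list(),
                          shared_voxel_set = integer(0),
                          motor_voxel_set = integer(0),
                          effect_sizes = c(target = 0.6, edge = 0.3,
                                           shared = 0.5, motor = 30),
                          noise_sd = 0.06,
                          baseline = c(primary = 0.92, control = 0.85,
                                       grip = 32),
                          grip_strength_sd = 8,
                          grip_noise_sd = 5) {
  stopifnot(all(is.finite(effect_sizes)), noise_sd >= 0)
  es <- c(target = 0, edge = 0, shared = 0, motor = 0)
  es[names(effect_sizes)] <- effect_sizes
  if (es[["target"]] != 0 && !length(target_voxel_set))
    stop("target_voxel_set empty but its effect size is nonzero")
  if (es[["edge"]] != 0 && !length(target_edges))
    stop("target_edges empty but its effect size is nonzero")
  if (es[["shared"]] != 0 && !length(shared_voxel_set))
    stop("shared_voxel_set empty but its effect size is nonzero")
  structure(list(
    target_voxel_set = target_voxel_set,
    target_edges = target_edges,
    shared_voxel_set = shared_voxel_set,
    motor_voxel_set = motor_voxel_set,
    effect_sizes = es,
    noise_sd = noise_sd,
    baseline = baseline,
    grip_strength_sd = grip_strength_sd,
    grip_noise_sd = grip_noise_sd
  ), class = "planted_model")
}

# Distance from point p to the segment a-b.
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
  sqrt(sum((p - t * ab - a)^2))
}

# Ball of territory voxels within `radius` of a (possibly fractional)
# center coordinate.
territory_ball <- function(territory, dims, center, radius) {
  co <- arrayInd(territory, dims)
  d2 <- rowSums((co - matrix(center, nrow(co), 3L, byrow = TRUE))^2)
  territory[d2 <= radius^2]
}

#' Default planted model derived from a parcellation
#'
#' The planted target region is a compact ball of voxels at the territory
#' core — where the cohort's lesions concentrate, so the region is
#' adequately covered and recoverable in principle (the analysis can only
#' see tissue lesioned in enough subjects, exactly as the real coverage
#' criterion dictates). The shared region driving the correlated control
#' score and the motor region driving right-hand grip are balls displaced
#' from the core along different axes. The planted disconnection effect
#' sits on the node pair whose centroid-to-centroid path passes closest to
#' the core, so lesions frequently interrupt it.
#'
#' @param parcellation A `parcellation`.
#' @param territory Linear voxel indices (default left hemisphere).
#' @param kind `"effect"` for the planted-effect defaults, `"null"` for a
#'   no-effect model (noise only).
#' @param noise_sd Overrides the default noise sd when not `NULL`.
#' @param core_radius Radius (voxels) of the planted regions.
#' @return A `planted_model` with extra fields `core` (the territory core
#'   coordinate) and `target_edge_nodes`.
#' @export
default_planted_model <- function(parcellation,
                                  territory = left_hemisphere_territory(parcellation),
                                  kind = c("effect", "null"),
                                  noise_sd = NULL, core_radius = 6,
                                  effect_sizes = c(target = 0.6, edge = 0.3,
                                                   shared = 0.5, motor = 30)) {
  kind <- match.arg(kind)
  dims <- parcellation$grid_shape
  core <- colMeans(arrayInd(territory, dims))
  shift <- max(4, round(core_radius * 1.3))
  tv <- territory_ball(territory, dims, core, core_radius)
  sv <- territory_ball(territory, dims, core + c(0, shift, 0), core_radius)
  mv <- territory_ball(territory, dims, core + c(0, -shift, 0), core_radius)
  # node pair whose straight path passes closest to the core, preferring
  # well-separated pairs so the edge is a genuine long-range connection
  ep <- edge_pairs(n_nodes(parcellation))
  cent <- parcellation$node_centroids
  dseg <- apply(ep, 1L, function(pr)
    point_segment_distance(core, cent[pr[1L], ], cent[pr[2L], ]))
  len <- apply(ep, 1L, function(pr)
    sqrt(sum((cent[pr[1L], ] - cent[pr[2L], ])^2)))
  ok <- len >= stats::median(len)
  best <- which(ok)[which.min(dseg[ok])]
  target_edge <- as.integer(ep[best, ])
  if (kind == "null") {
    m <- planted_model(effect_sizes = c(target = 0, edge = 0, shared = 0,
                                        motor = 0),
                       noise_sd = if (is.null(noise_sd)) 0.08 else noise_sd)
  } else {
    m <- planted_model(
      target_voxel_set = tv,
      target_edges = list(target_edge),
      shared_voxel_set = sv,
      motor_voxel_set = mv,
      effect_sizes = effect_sizes,
      noise_sd = if (is.null(noise_sd)) 0.06 else noise_sd
    )
  }
  m$core <- core
  m$target_edge_nodes <- target_edge
  m
}

# Fractional lesion load of a voxel set: |lesion intersect set| / |set|.
fractional_load <- function(lesion_lgl, voxel_set) {
  if (!length(voxel_set)) return(0)
  mean(lesion_lgl[voxel_set])
}

# Mean disconnection of specific node pairs for one lesion (logical vector).
planted_edge_loss <- function(lesion_lgl, atlas, pairs) {
  if (!length(pairs)) return(0)
  mean(vapply(pairs, function(pr) {
    refs <- atlas$paths[[edge_id(pr[1L], pr[2L])]]
    mean(vapply(refs, function(rf) sum(rf$p[lesion_lgl[rf$vox]]), numeric(1)))
  }, numeric(1)))
}

#' Generate a synthetic lesion cohort with planted behavioral effects
#'
#' Lesion volumes are drawn log-normally (defaults calibrated to the
#' published cohort's volume range rescaled to the toy grid); lesion start
#' points are concentrated around a territory core to emulate the overlap
#' structure of a single-artery stroke cohort. Behavioral scores follow the
#' planted model: primary = baseline - target-load and planted-edge effects
#' + noise; control = baseline - shared-load effect + noise; grips share a
#' per-subject strength factor and the right hand additionally loses
#' strength with motor-set load. Proportion scores are clipped to [0, 1]
#' and grips to >= 0; months post-stroke is drawn independently.
#'
#' @param parcellation A `parcellation`.
#' @param atlas A `ref_path_atlas` (needed when planted edge effects are
#'   nonzero; may be `NULL` otherwise).
#' @param model A `planted_model`.
#' @param n_subjects Cohort size (>= 10 recommended; default 57).
#' @param volume_distribution List with `meanlog`, `sdlog`, `min`, `max`
#'   (voxel counts).
#' @param seed Integer seed.
#' @param territory Linear voxel indices lesions may occupy.
#' @param core_sd Sd (voxels) of the Gaussian concentration of lesion start
#'   points around the territory core.
#' @param lesions Optional pre-made list of `lesion_mask` (skips lesion
#'   generation; scores are computed for these masks).
#' @return List with `lesions` (list of `lesion_mask`) and `behavior`
#'   (a `behavior_table` data frame).
#' @export
generate_cohort <- function(parcellation, atlas = NULL, model,
                            n_subjects = 57L,
                            volume_distribution = list(meanlog = log(300),
                                                       sdlog = 1.0,
                                                       min = 5, max = 2500),
                            seed = 1L,
                            territory = left_hemisphere_territory(parcellation),
                            core_sd = NULL,
                            lesions = NULL) {
  stopifnot(inherits(model, "planted_model"))
  dims <- parcellation$grid_shape
  if (is.null(core_sd)) core_sd <- dims[1L] / 8
  terr_lgl <- logical(prod(dims))
  terr_lgl[territory] <- TRUE
  with_seed(seed, {
    if (is.null(lesions)) {
      n <- as.integer(n_subjects)
      vols <- round(pmin(pmax(stats::rlnorm(n, volume_distribution$meanlog,
                                            volume_distribution$sdlog),
                              volume_distribution$min),
                         volume_distribution$max))
      core <- colMeans(arrayInd(territory, dims))
      co <- arrayInd(territory, dims)
      d2 <- rowSums((co - matrix(core, nrow(co), 3L, byrow = TRUE))^2)
      wstart <- exp(-d2 / (2 * core_sd^2))
      starts <- territory[sample.int(length(territory), n, replace = TRUE,
                                     prob = wstart)]
      geom <- grid_geometry(dims)
      lesions <- lapply(seq_len(n), function(s) {
        new_lesion_mask(grow_lesion(dims, terr_lgl, vols[s], starts[s], geom),
                        sprintf("S%03d", s))
      })
    } else {
      n <- length(lesions)
    }
    les_lgl <- lapply(lesions, function(l) as.logical(l$mask))
    load_t <- vapply(les_lgl, fractional_load, numeric(1),
                     voxel_set = model$target_voxel_set)
    load_s <- vapply(les_lgl, fractional_load, numeric(1),
                     voxel_set = model$shared_voxel_set)
    load_m <- vapply(les_lgl, fractional_load, numeric(1),
                     voxel_set = model$motor_voxel_set)
    es <- model$effect_sizes
    edge_loss <- if (es[["edge"]] != 0) {
      stopifnot(!is.null(atlas))
      vapply(les_lgl, planted_edge_loss, numeric(1),
             atlas = atlas, pairs = model$target_edges)
    } else rep(0, n)
    primary <- model$baseline[["primary"]] -
      es[["target"]] * load_t - es[["edge"]] * edge_loss +
      stats::rnorm(n, 0, model$noise_sd)
    control <- model$baseline[["control"]] -
      es[["shared"]] * load_s + stats::rnorm(n, 0, model$noise_sd)
    strength <- stats::rnorm(n, model$baseline[["grip"]],
                             model$grip_strength_sd)
    lh <- pmax(strength + stats::rnorm(n, 0, model$grip_noise_sd), 0)
    rh <- pmax(strength - es[["motor"]] * load_m +
                 stats::rnorm(n, 0, model$grip_noise_sd), 0)
    behavior <- data.frame(
      subject_id = vapply(lesions, `[[`, "", "subject_id"),
      gts_hp = pmin(pmax(primary, 0), 1),
      imi_hp = pmin(pmax(control, 0), 1),
      lh_grip = round(lh, 2),
      rh_grip = round(rh, 2),
      months_post = round(pmin(pmax(stats::rlnorm(n, log(22), 1.0), 3), 200)),
      lesion_volume = vapply(lesions, `[[`, 0L, "volume"),
      age = round(pmin(pmax(stats::rnorm(n, 56, 11.5), 31), 80)),
      education = round(pmin(pmax(stats::rnorm(n, 14.2, 2.8), 9), 21)),
      gender = sample(c("F", "M"), n, replace = TRUE, prob = c(28, 29) / 57),
      stringsAsFactors = FALSE
    )
    class(behavior) <- c("behavior_table", "data.frame")
    list(lesions = lesions, behavior = behavior)
  })
}
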