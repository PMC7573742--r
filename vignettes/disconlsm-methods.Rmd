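---
title: "Multivariate lesion-symptom mapping with structural disconnectomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate lesion-symptom mapping with structural disconnectomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

After a left-hemisphere stroke, the ability to pantomime tool use can be
impaired out of proportion to elementary motor loss (limb apraxia). Two
complementary questions arise: *where* does tissue damage predict worse
tool-use gesturing, and *which white-matter connections*, when
interrupted, predict it? `disconlsm` implements the full analysis chain
for both questions:

1. **SVR-VLSM** — all voxels' binary lesion status across the cohort enter
   one support vector regression against a residualized behavioral score;
   per-voxel weights are z-scored against a Monte Carlo permutation null,
   thresholded one-tailed, and filtered by cluster extent.
2. **Disconnectome construction** — each lesion is intersected with a
   reference shortest-path tractography atlas: for node pair $(i, j)$ and
   reference subject $r$, the loss is
   $\ell_r = \sum_{v \in \text{lesion}} p_r(v) \big/ \sum_v p_r(v)$,
   and the pair's disconnection is the mean of $\ell_r$ over reference
   subjects — a value in $[0, 1]$, 1 meaning complete disconnection.
3. **SVR-CLSM** — edge disconnection values, residualized on nuisance
   factors, enter the same SVR/permutation machinery; surviving edges are
   reduced to a *maximally disconnected subgraph* and node-level
   disconnection counts.
4. **Seed-node screen** — remote nodes whose residual disconnection from a
   chosen seed predicts behavior, filtered by three sequential criteria
   (outside the lesion territory; one-tailed correlation $p<.05$;
   permutation $z < -1.96$).

The behavioral side packages the published cohort table (57 participants:
tool-use and imitation hand-posture scores, grip strength for 41,
demographics, lesion volumes) and the residualization conventions: the
voxel analyses use the primary score residualized on its control score
(imitation for tool use; left-hand grip for right-hand grip), and the edge
analyses additionally residualize out total lesion volume.

## The SVR engine

The engine is one code path for voxels and edges.

* **Kernel.** Gaussian kernel
  $K(x, x') = \exp(-\lVert x - x' \rVert^2 / s^2)$ with kernel scale
  $s = 1$ by default (a linear kernel is available). Because the kernel
  depends only on the features, it is computed **once** per data set and
  sliced per fold — this is what makes 10,000-iteration permutation runs
  tractable (a fold fit takes ~5 ms at $n = 57$).
* **Fitting.** Epsilon-insensitive SVR (kernlab's `ksvm` on the
  precomputed kernel). Defaults: box constraint $C = 1$ and tube
  $\epsilon = 0.1\,\mathrm{sd}(y)$. Neither is prescribed by the method's
  lineage, so both are exposed in `svr_config()`. The target is
  standardized before fitting (configurable) so $s$ and $\epsilon$ are
  comparable across behavioral measures. A target lying entirely inside
  the tube has the exact solution $\alpha = 0$; the code short-circuits
  that case rather than treating it as an error.
* **Back-projection.** An RBF model has no finite-dimensional beta map, so
  per-feature weights use the linear back-projection of the dual
  coefficients onto training rows, $w = X^\top \alpha$ — the convention of
  published SVR-LSM implementations, reproducible and kernel-agnostic.
* **Cross-validation.** Subjects are partitioned into 5 seeded folds; each
  fold's model is trained on the other 80% and back-projected; the final
  map is the mean of the 5 fold maps.
* **Permutation z-scores.** For each of `n_permutations` iterations the
  target vector is shuffled across subjects, the fold assignment
  re-randomized, and the cross-validated map recomputed;
  $z_j = (w_j - \bar w^{null}_j) / \mathrm{sd}(w^{null}_j)$. Re-randomizing
  folds makes the null absorb fold-partition variance as well as
  target-exchange variance (set `refold = FALSE` to reuse the true run's
  folds). Features with degenerate null sd get $z = 0$ and a flag.
  Permutations shuffle the already-residualized target; nuisance
  regression is *not* re-run inside the loop.

## Voxel analysis choices

* **Coverage.** A voxel (or edge) enters only if lesioned in at least 10%
  of the cohort; the count threshold is $\max(1, \lfloor 0.1 n \rfloor)$.
  The floor rule reproduces the conventional printed counts (5 of 57;
  4 of 41); the extra floor of 1 only matters for cohorts under 10.
* **dTLVC.** Direct total lesion volume control scales subject $i$'s
  binary lesion vector by $1/\sqrt{V_i}$ (unit Euclidean norm), removing
  the mechanical effect of lesion size. `run_vlsm` uses the subject's
  *total* lesion volume, so a subject whose lesion misses the coverage
  mask contributes an (empty) scaled row rather than an error.
* **Threshold and extent.** Strict $z < -1.65$ (one-tailed $P < .05$),
  then connected components under 26-connectivity ("contiguous" read
  permissively, as is standard in lesion mapping; 6/18 exposed), dropping
  components below the extent criterion. At full resolution the criterion
  is 500 contiguous 1 mm³ voxels; on a toy grid it scales with grid volume
  relative to a 181×217×181 reference with a floor of 5 voxels
  (`scale_min_cluster()`). Cluster peaks are the most negative z; centers
  of mass are unweighted mean voxel coordinates.

## Disconnectome and edge analysis choices

* An edge counts as "lesioned" for the coverage rule when its
  disconnection is strictly positive; there is no implicit floor (one is
  exposed via `min_disconnect` for sensitivity checks).
* Node pairs with no reference connectivity are flagged unconnected and
  excluded rather than imputed as zero-variance columns.
* Edge matrices use a fixed lexicographic upper-triangle order
  (1,2),(1,3),…,(2,3),… with "i|j" column names serialized into every
  output, so matrices are bit-reproducible.
* The nuisance design for the edge SVR is: cumulative disconnection of the
  regions implicated by the voxel analysis (sum over unique edges with at
  least one endpoint in the region set), total lesion volume, and months
  post-stroke, with an intercept. Per-edge OLS residuals feed the SVR.
* **Maximally disconnected subgraph.** Defined as the connected subgraph
  of surviving edges maximizing total $|z|$. Because all surviving weights
  are positive, adding an edge never lowers the objective, so the exact
  optimum is the heaviest connected component — the `"exact"` solver
  evaluates every component and is verified against brute-force
  enumeration over all connected edge subsets in the test suite. A
  `"greedy"` solver (grow from the heaviest edge) is provided for
  contrast; it can settle for the heaviest edge's component. `"auto"`
  uses exact up to 15 nodes.

## Seed-node screen choices

* Criterion 1 reads "overlap with the lesion territory" as the fraction of
  node voxels lesioned in ≥1 subject (a count-weighted variant is exposed).
* Criterion 2 is implemented as one-tailed $p < .05$ for the negative
  direction. At $n = 57$ the implied boundary is $r \approx -0.22$.
* Criterion 3 z-scores the observed correlation against a seeded
  permutation null of the behavior vector; since the null sd of $r$ is
  $\approx 1/\sqrt{n-1}$, an edge with $r = -0.24$ lands near $z = -1.8$:
  significant by criterion 2 yet failing criterion 3 — the structurally
  interesting borderline case the report preserves with full diagnostics.
* The final pass set is a pure conjunction, so criterion order is
  irrelevant; the report keeps all candidate rows with per-criterion flags.

## The synthetic cohort generator

Real lesions and disconnectomes for the published cohort are not publicly
archived, so the package ships a fully seeded generator whose defaults
encode the study conditions at desk scale:

* **Grid and parcellation:** 32×32×32 voxels, 12 nodes grown as connected
  blobs by seeded random accretion; lesions are confined to the low-x half
  ("left hemisphere"). These sizes keep a 20-cohort calibration run in
  minutes on one CPU while leaving room for meaningful clusters.
* **Reference path atlas:** for each node pair, each of `n_reference`
  (20 in the simulation studies — a desk-scale stand-in for a large
  tractography cohort) reference subjects contributes a rasterized
  centroid-to-centroid chain, laterally jittered (sd 1 voxel), with
  core-peaked visitation probabilities normalized to 1.
* **Lesions:** single 26-connected blobs grown by random accretion.
  Volumes are log-normal (median 300 voxels, sd log 1.0, clipped to
  [5, 2500]) — the published cohort's volumes span 337–303,310 mm³ on a
  ~7·10⁶-voxel brain, i.e. roughly 10⁻⁴ to 10⁻¹ of the hemisphere, and the
  toy defaults reproduce that relative spread. Start points concentrate
  around the territory core (Gaussian, sd = 4 voxels) to emulate the
  overlap structure of a single-artery cohort; the lognormal family itself
  is a package choice (the source table prints only ranges).
* **Behavior:** primary score = baseline − target-load effect −
  planted-edge effect + Gaussian noise; control score = baseline −
  shared-load effect + noise; grips share a per-subject strength factor
  with a motor-set loss on the right hand. Proportions are clipped to
  [0, 1], grips to ≥ 0; months post-stroke is drawn independently of
  behavior (it is a nuisance covariate, not a modeled effect). Noise is
  homoscedastic Gaussian — the simplest model consistent with OLS
  residualization. With the default effect sizes the primary/control
  correlation across cohorts averages ≈ 0.31 (inside the plausible 0.2–0.7
  band around the published r = 0.41).
* **Planted regions:** compact voxel balls at/near the territory core —
  where the cohort's lesions concentrate — so that planted effects are in
  principle recoverable (the analysis can only see tissue lesioned in
  ≥10% of subjects). The planted edge is the node pair whose
  centroid-to-centroid path passes closest to the core.

What the generator does **not** emulate: vascular-territory lesion shapes,
registration error, diffusion signal, right-hemisphere or interhemispheric
disconnection, and item-level behavioral structure. Passing recovery tests
therefore show the pipeline's statistical machinery behaves as specified
on data satisfying its assumptions, not that the method is unbiased on
real stroke anatomy.

## Simulation studies and their scales

* `null_calibration()`: 20 effect-free cohorts (n = 57) at 500
  permutations; the fraction of features below z = −1.65 averages ≈ 5%
  at the voxel level and ≈ 3–5% at the edge level (edge counts are small,
  so per-cohort fractions are coarse). Null cohorts routinely produce a
  few above-extent clusters at the desk-scale extent floor of 5 voxels —
  the 500-voxel full-resolution criterion is far stricter relative to its
  grid than 5 voxels is to 32³, a known desk-scale limitation.
* `planted_recovery()`: per seed, one voxel-effect cohort (VLSM Dice
  against the planted region) and one edge-effect cohort run through the
  full pipeline (rank of the planted edge among negative z-scores), at
  150 permutations. The planted edge ranks first in essentially every
  seed. Top-cluster Dice concentrates around 0.3–0.45: the permutation
  threshold detects only part of the planted ball (subjects grazing the
  ball with small lesions carry little behavioral load) and the surviving
  cluster adds a correlated shell at the lesion-size blur scale. This
  mislocalization floor is a property of multivariate lesion-symptom
  mapping at n = 57, not of the implementation; the package reports the
  measured Dice honestly rather than restating an aspirational bound.

## Numerical choices

* All generators and permutation loops are pure functions of their seeds;
  the RNG state of the caller is saved and restored.
* Zero-variance guards: correlations error on constant input; zero-variance
  edge columns are excluded with flags; degenerate permutation nulls
  (relative sd below 10⁻⁶) give z = 0 plus a flag.
* OLS residualization uses a QR decomposition with an explicit intercept
  and errors on rank-deficient designs, naming the collinear columns.
* Cluster extraction uses strict inequalities at both thresholds, so a
  voxel exactly at z = −1.65 (or a cluster exactly below the extent
  criterion) is excluded.
* Coordinates are 1-based inside R (array convention) and exported 0-based
  in TSV artifacts; the manifest records the convention.

## Known limitations

* Grip analyses use pairwise-complete rows (41 of 57) with no imputation.
* The subgraph objective is a declared reading of "greatest shared
  disconnection" (maximum total |z| over connected subgraphs); other
  published subgraph extractions may differ.
* Whether reference-subject averaging should pool probabilities before
  taking the loss ratio (rather than averaging per-subject ratios, as
  implemented) is unresolved; the per-subject form is the stated choice.
* The desk-scale cluster-extent floor is permissive (see above); the
  500-voxel criterion is preserved verbatim for full-resolution grids.
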