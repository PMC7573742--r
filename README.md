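# disconlsm

Multivariate lesion-symptom mapping with structural disconnectomes, for
stroke-cohort studies that ask two linked questions: *where* does tissue
damage predict a behavioral deficit (voxel level), and *which white-matter
connections*, when interrupted, predict it (connectome level)?

The motivating application is limb apraxia after left-hemisphere stroke —
impaired tool-use gesturing that is not reducible to elementary motor
loss — studied in a published cohort of 57 participants whose behavioral
and demographic table ships with the package. Because that study's lesions
and disconnectomes are not publicly archived, the package pairs the
analysis chain with a fully seeded synthetic cohort generator so every
statistical property of the pipeline is testable end to end.

## What it implements

* **SVR-VLSM** (`run_vlsm`): binary lesion masks across the cohort enter a
  single epsilon-insensitive support vector regression (Gaussian kernel,
  kernel scale 1) against a residualized behavioral score, with

  * a 10% lesion-coverage inclusion mask (`coverage_mask`),
  * direct total lesion volume control — each subject's lesion vector
    scaled to unit norm, `1/sqrt(volume)` (`dtlvc_scale`),
  * 5-fold averaged back-projected weight maps (`crossval_weight_map`),
  * Monte Carlo permutation z-scores (`permutation_zscores`),
  * one-tailed thresholding at z < −1.65 plus a cluster-extent filter
    under 26-connectivity (`threshold_and_cluster`), and
  * atlas labeling of surviving clusters (`label_clusters`).

* **Disconnectomes** (`edge_disconnection`, `batch_disconnectomes`): a
  lesion intersected with a reference shortest-path tractography atlas
  gives, per node pair, the proportional loss of path probability, averaged
  over reference subjects — a symmetric node×node matrix in [0, 1].

* **SVR-CLSM** (`run_clsm`): edge disconnection residualized on cumulative
  disconnection of the voxel-analysis regions, total lesion volume and
  months post-stroke (`nuisance_residualize_edges`), then the same
  SVR/permutation machinery; surviving edges reduce to a maximally
  disconnected subgraph (`max_disconnected_subgraph`) and node-level
  disconnection counts (`node_disconnection_count`).

* **Seed-node screen** (`build_seed_report`): remote nodes whose residual
  disconnection from a chosen seed predicts behavior, filtered by three
  sequential criteria — <1% overlap with the lesion territory, one-tailed
  correlation p < .05 (boundary r ≈ −0.22 at n = 57), and permutation
  z < −1.96.

* **Synthetic cohorts** (`generate_parcellation`,
  `generate_reference_paths`, `generate_lesion`, `generate_cohort`,
  `default_planted_model`): seeded toy anatomy, path atlases, lesion blobs
  and planted-effect behavior; plus study-level experiments
  (`null_calibration`, `planted_recovery`, `score_correlation_structure`).

`run_full_pipeline()` wires the stages together for the two study
analyses (`"tool_use"`, `"grip"`), writes TSV artifacts plus a JSON
provenance manifest, and degrades gracefully to behavior-only artifacts
when no lesion data are supplied.

## Worked example

```r
library(disconlsm)

# behavioral statistics of the packaged 57-participant cohort table
tab <- load_table1_fixture()
pearson_r(tab$gts_hp, tab$imi_hp)
#> [1] 0.4092353
cc <- complete.cases(tab$lh_grip, tab$rh_grip)
pearson_r(tab$rh_grip[cc], tab$lh_grip[cc])
#> [1] 0.4754703

# synthetic end-to-end run with a planted disconnection effect
an    <- study_anatomy()                      # 32^3 grid, 12 nodes
model <- default_planted_model(an$parcellation, an$territory, "effect",
                               noise_sd = 0.02)
cohort <- generate_cohort(an$parcellation, an$atlas, model, seed = 7,
                          territory = an$territory)
bundle <- run_full_pipeline(cohort$behavior, cohort$lesions,
                            an$parcellation, an$atlas, "tool_use",
                            svr_config(n_permutations = 100, seed = 7))
bundle$vlsm
#> voxel_stat_map: 2620 voxels in mask; 4 cluster(s) surviving z < -1.65 and extent >= 5
bundle$subgraph
#> subgraph (exact): 5 nodes, 4 edges, total |z| = 14.227
```

The first correlation says tool-use and imitation hand-posture scores
share variance (r ≈ 0.41 in the cohort), which is why the mapping analyses
use tool-use scores residualized on imitation. In the synthetic run the
voxel map recovers clusters around the planted core region and the
subgraph collects the significant disconnection edges with the planted
edge carrying the largest |z|.

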