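Package: disconlsm
Title: Multivariate Lesion-Symptom Mapping with Structural Disconnectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Support-vector-regression lesion-symptom mapping at the voxel
    (SVR-VLSM) and connectome (SVR-CLSM) level for left-hemisphere stroke
    cohorts, with Monte Carlo permutation z-scoring, direct total lesion
    volume control, cluster-extent thresholding and atlas labeling.
    Disconnectomes are built by intersecting binary lesion masks with a
    reference shortest-path tractography atlas; significant edges are
    reduced to a maximally disconnected subgraph, and a post-hoc seed-node
    screen relates remote-node disconnection to behavior. Includes a fully
    seeded synthetic cohort generator (parcellation, path atlas, lesion
    blobs, planted behavioral effects) for calibration and recovery
    studies, and a packaged behavioral table for a published 57-participant
    stroke cohort.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    kernlab,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
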