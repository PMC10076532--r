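Package: metconn
Title: Inter-Subject Metabolic Connectivity Networks of the Default Mode Network
Version: 1.0.0
Authors@R:
    person("metconn", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and group comparison of inter-subject metabolic
    (FDG-PET covariance) connectivity networks over 14 default mode network
    volumes of interest. Extracts intensity-normalized regional uptake from
    MNI-space NIfTI or Analyze volumes (or a pre-extracted subject-by-region
    table), builds per-group weighted undirected Pearson correlation networks
    with their Fisher z transforms, characterizes them with weighted graph
    metrics (global and nodal efficiency, characteristic path length, degree
    centrality), and compares groups with label-permutation tests under
    Benjamini-Hochberg false discovery rate control. Includes a synthetic
    cohort simulator (multivariate normal uptake with planted edge effects,
    optional voxel-volume rendering) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
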