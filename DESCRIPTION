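Package: abpose
Title: Equivariant Graph Scoring of Antibody-Antigen Binding Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts immunoglobulin-antigen complex structures into
    interface-focused residue graphs and scores candidate binding poses with an
    E(n)-equivariant graph neural network. Provides a binary classifier of
    native-like versus non-native poses and a regressor estimating DockQ-scale
    pose quality, together with interface k-hop subgraph sampling, selective
    weighted pooling, composite classification and regression objectives
    (cross-entropy, Pearson-correlation and listwise ranking terms),
    checkpoint ensembling, and a filter-then-rank candidate selection
    pipeline. Includes a DockQ implementation for labeling and evaluation and
    a synthetic complex/decoy generator so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tibble,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
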