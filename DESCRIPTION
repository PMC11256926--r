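Package: trajflow
Title: Trajectory Inference for Short Clinical Time Series Transcriptomics
    via Multi-Commodity Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pseudotime ordering and endotype discovery for clinical
    time-series transcriptomics cohorts profiling few visits per patient.
    Samples are embedded by PCA, connected by a UMAP-style fuzzy simplicial
    nearest-neighbor graph, and clustered into disease states with Leiden
    community detection. Each patient's consecutive-visit sample pairs are
    routed as commodities through the graph by a capacity-constrained
    fractional multi-commodity flow linear program; per-patient paths are
    aggregated into a state-transition diagram from which the most likely
    disease or treatment trajectories are ranked. Includes TMM/CPM
    preprocessing, a Kolmogorov-Smirnov gene score with prerank export, a
    synthetic-cohort generator with planted trajectories for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    edgeR,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with scipy, on the PATH as 'python' or
    'python3' (LP solver backend, HiGHS via scipy.optimize.linprog)
Config/testthat/edition: 3
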