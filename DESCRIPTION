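Package: kinoflex
Title: Flexibility and Activity Analysis of Protein Kinase Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline relating conformational flexibility to the
    activation state of tyrosine kinases. Computes per-residue backbone
    root-mean-square fluctuations (RMSF) from multi-model trajectories,
    maps them onto common multiple-sequence-alignment columns, and learns
    an interpretable one-rule (decision-stump) classifier separating
    active from inactive kinases, with repeated-holdout evaluation,
    feature ablation and L1-logistic corroboration. Also summarises
    binding-pocket dynamics from merge/split event logs (connection
    matrices, time-averaged volumes, Welch group comparisons) and
    clusters activation-loop conformations with k-medoids on pairwise
    RMSD, including cluster-transition graphs. A synthetic-data module
    generates trajectories, fluctuation panels, activity series and
    pocket event streams with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
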