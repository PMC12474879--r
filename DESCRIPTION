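Package: chronosere
Title: Abundant, Intermediate and Rare Soil Bacterial Subcommunities Along
    Restoration Chronosequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of soil bacterial subcommunities along ecological
    restoration chronosequences from amplicon sequence variant (ASV) count
    tables. Provides multivariate cutoff level analysis and abundance-based
    classification of abundant, intermediate and rare taxa; Levins and
    tolerance niche-breadth indices; Bray-Curtis community statistics with
    Baselga's balanced-variation/abundance-gradient partition, NMDS, ANOSIM,
    SIMPER and Mantel tests; null-model quantification of community assembly
    processes (beta nearest taxon index and abundance-weighted Raup-Crick);
    SparCC compositional correlation networks with module-based keystone
    classification and robustness; ecosystem multifunctionality indices; and
    piecewise path models with composite variables and Fisher's C
    d-separation test. Includes a synthetic chronosequence generator with
    known ground truth for validating every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    minpack.lm,
    phytools,
    stats,
    tools,
    utils,
    vegan
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
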