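Package: tbsmap
Title: Transient Binding Site Mapping from Protein-Ligand Contact Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transient ligand-binding sites on an enzyme surface from
    molecular-dynamics contact time series and designs small, rationally
    filtered single-point mutant libraries. Per-frame enzyme-ligand contacts
    (from multi-model PDB trajectories or precomputed contact tables) are
    stored as sparse binary residue-by-frame matrices, clustered in two
    hierarchical stages under the Jaccard distance into local clusters and
    global binding sites, filtered by interaction-time and pathway-exclusion
    rules into key residues, and combined with a folding free-energy change
    table and a physicochemical-change score into a ranked mutant library.
    Includes a seeded synthetic contact-matrix generator with planted binding
    sites for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    Matrix,
    stats,
    utils,
    generics,
    ggplot2,
    withr,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
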