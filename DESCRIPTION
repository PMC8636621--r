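Package: mdcna
Title: Difference Contact Network Analysis of Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residue-level dynamic network analysis of multi-state
    conformational ensembles from molecular dynamics. Computes
    contact-probability maps with persistent-contact identification and
    chemical classification, consensus networks across functional states,
    Girvan-Newman community detection with a modularity-convergence
    stopping rule, difference contact network analysis (per-transition
    community-pair contact-probability changes), correlation-weighted
    dynamic networks with suboptimal allosteric-path enumeration, and
    structural metrics (Shrake-Rupley solvent-accessible and buried
    surface area, ensemble B-factors, duplex rotation angles, and
    map-to-model cross-correlation against CCP4/MRC density maps). A
    seeded planted-community ensemble generator provides ground-truth
    data for validating every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
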