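Package: dualprofiler
Title: Post-Docking Binding Profiles, Combinatorial Libraries and
    Dual-Target Virtual-Screening Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing docked protein-ligand complexes and for
    evaluating dual-target virtual screens. Computes per-residue binding
    profiles from buried accessible surface area (Shrake-Rupley), heavy-atom
    non-bonded contacts and distance-based hydrogen bonds; identifies key
    binding-site residues and compares interacting-residue sets across
    ligands; enumerates scaffold plus R-group combinatorial libraries with
    rule-of-five drug-likeness descriptors; ranks dock-score tables, selects
    dual-target consensus compounds, converts binding free energies to pKd,
    and measures screening quality with decoy-based enrichment factors and
    enrichment curves. Ships a synthetic-data generator that plants contacts,
    hydrogen bonds, buried surface and score separations with a ground-truth
    ledger so every stage is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
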