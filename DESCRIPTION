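Package: ctpairs
Title: Compound-Target Interaction Pairs from ChEMBL-Schema Stores
Version: 0.1.0
Authors@R: person("ctpairs", "maintainers", email = "ctpairs@example.org",
    role = c("aut", "cre"))
Description: Reproducible extraction of an annotated compound-target pairs
    dataset from a ChEMBL-schema SQLite database. Activity records measured
    in binding or functional assays are mapped to parent compounds and
    aggregated into per-pair pChEMBL summaries; manually curated
    mechanism-of-action interactions are merged in and every pair is
    assigned a drug-target interaction (DTI) class. Compound structures,
    physicochemical properties, ligand-efficiency metrics (LE, BEI, SEI,
    LLE), ATC codes, protein target classes and optional RDKit-based
    descriptors are attached. The assembled dataset is cleaned, validated
    with consistency checks, and written together with filter-defined
    subsets and per-dataset statistics. A fixture generator builds
    miniature ChEMBL-schema stores with an independent brute-force ground
    truth so that the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    DBI,
    RSQLite,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    writexl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
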