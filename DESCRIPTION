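Package: pharmscreen
Title: Pharmacophore Modeling, Virtual-Screening Validation and
    Binding-Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A ligand- and structure-based pharmacophore screening toolkit
    for kinase inhibitor discovery. Perceives pharmacophore features
    (donors, acceptors, hydrophobes, aromatic rings, ionizable groups)
    from 3D small molecules with an explicit, overridable SMARTS rule set;
    enumerates common-feature hypotheses from a training set of actives by
    clique search on feature-correspondence graphs; derives
    structure-based hypotheses from receptor-ligand interaction geometry;
    maps and screens compound libraries with a tolerance-weighted fit
    score; validates hypotheses with ROC and Guner-Henry decoy-set
    statistics; applies rule-of-five and surrogate ADMET gates; aggregates
    MM-PBSA-style snapshot energies into ranked binding summaries; and
    analyses trajectory stability via Kabsch superposition, RMSD and RMSF.
    Seeded synthetic-data generators emulate every input so the whole
    funnel is testable without commercial tools or proprietary databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    bio3d,
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
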