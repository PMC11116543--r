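Package: capscore
Title: Computer-Aided Pattern Scoring for Ligand-Based Virtual Screening
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Substructure-pattern occurrence analysis and scoring for
    ligand discovery at sparsely annotated ("orphan") targets. Provides
    curation and deduplication of compound tables, a substructure catalog
    engine with defined-hydrogen and attachment-point semantics, collective
    pattern analysis over compound groups, rule-based extraction of a
    focused fingerprint, conjunctive library filtering with binary
    pattern-distribution scoring, scaffold-class candidate selection,
    physicochemical drug-likeness statistics, and hit calling with
    closed-form two-point IC50 estimation under the three-parameter
    logistic model. A deterministic synthetic-fixture generator with known
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, ChemmineR, ChemmineOB
Suggests: testthat (>= 3.0.0), withr, minpack.lm, optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, Software
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'bioval.R'
    'capscore-package.R'
    'chem-io.R'
    'fixtures.R'
    'ob-utils.R'
    'pattern-analysis.R'
    'physchem.R'
    'pipeline.R'
    'screening.R'
    'smiles-graph.R'
    'substructure-engine.R'
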