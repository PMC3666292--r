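Package: sspipe
Title: Protein Secondary-Structure Prediction from PSSM and Physicochemical Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested toolkit for three-state protein secondary-structure
    prediction. Encodes residues with sliding windows over PSI-BLAST
    position-specific scoring matrix (PSSM) profiles plus conformational
    propensities, net charge, Kyte-Doolittle hydropathy and side-chain mass;
    classifies with a one-vs-one radial-basis-function support vector machine
    under max-wins voting; refines predictions with consensus-length filter
    rules; and evaluates with Q3, per-class precision/recall and the 1994 and
    1999 segment-overlap (SOV) scores. Includes DSSP 8-to-3 state reductions,
    a PSI-BLAST ASCII PSSM parser/writer, a grid-search and chain-level
    cross-validation harness, and a synthetic-data generator so the whole
    pipeline is exercisable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
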