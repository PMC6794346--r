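Package: evtmt
Title: TMT Proteomics and Tau Immunoassay Analysis of CSF Extracellular Vesicles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for isobaric-label (TMT 10-plex) proteomics of
    cerebrospinal-fluid extracellular vesicles and paired tau immunoassays:
    in-silico tryptic digestion and reversed-decoy database construction,
    linear-discriminant rescoring of peptide-spectrum matches with
    target-decoy false-discovery-rate control at the PSM and protein level,
    parsimony protein inference with razor-peptide assignment, reporter-ion
    quantitation with explicit exclusion rules, group-wise differential
    abundance (Mann-Whitney with Bonferroni adjustment, fold-change
    thresholds, Pearson/average-linkage clustering), and four-parameter
    logistic calibration with dilution-corrected back-calculation for tau
    immunoassay data. A synthetic-data module generates every pipeline input
    with known ground truth so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    minpack.lm,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
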