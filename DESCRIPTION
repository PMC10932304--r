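Package: diliternary
Title: Ternary Metabolomic Phenotyping of Drug-Induced Liver Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for metabolomics-based phenotyping of drug-induced liver
    injury (DILI) from LC-MS peak tables and clinical chemistry. Implements
    QC-based support-vector-regression drift correction within batches,
    Welch/FDR univariate screening, a three-model one-vs-rest PLS-DA ensemble
    with subject-wise double cross-validation, latent-variable selection and
    VIP feature refitting, projection of the three model predictions onto
    ternary (cholestatic / hepatocellular / recovered) percentage coordinates,
    residual-DILI flagging in clinically recovered samples, and longitudinal
    transition monitoring. A synthetic-cohort generator with ground-truth
    phenotype mixtures makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
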