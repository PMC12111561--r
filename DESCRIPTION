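Package: renoquant
Title: Quantitation Pipeline for Renal Protection Studies in the Rat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the image, ultrasound, physiology and expression
    quantitation used in rat renoprotection studies of subclinical chronic
    kidney disease with superimposed ischaemia-reperfusion injury:
    dark-frame/flat-field background correction and Otsu segmentation of
    immunofluorescence micrographs; normalised RECA1 peritubular capillary
    scoring with luminal hole-filling; nuclear PGC-1alpha and normalised
    COX4 co-localisation scores; power-Doppler relative blood volume;
    kidney functional reserve and creatinine-normalised urinary biomarkers;
    2^ddCt relative expression with dual-housekeeping geometric-mean
    normalisation and mitochondrial DNA copy ratios; and Pearson screening
    plus (LASSO-)logistic group discrimination with bootstrap AUC
    confidence intervals. A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
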