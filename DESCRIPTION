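Package: pepccs
Title: Peptide Collision Cross Section Prediction with a Two-Branch
    Convolutional Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts peptide collision cross sections (CCS) observed in ion
    mobility spectrometry from the amino-acid sequence and charge state.
    Provides a comprehensive sequence featurization (45 per-residue
    descriptors, cumulative prefix/suffix features, a fixed-length
    323-channel spatial encoding and a multi-scale global feature vector), a
    two-branch convolutional + dense neural network trained with Adam on
    mean absolute error, ensemble averaging, the standard accuracy measures
    (RMSE, MAE, MPE, MdPE, Delta90, R-squared, Pearson r), conversion of CCS
    to drift times via a Mason-Schamp-type calibration, and a synthetic
    tryptic-peptide generator with a known ground-truth CCS function so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
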