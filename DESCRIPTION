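Package: cvmStager
Title: Cervical Vertebral Maturation Staging from Radiograph-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the cervical vertebral maturation (CVM) stage (CS1-CS6)
    from lateral-radiograph-like grayscale images. Provides a synthetic
    vertebra-image generator with ground-truth cephalometric landmarks, the
    preprocessing operators used for such images (cropping, resizing, Sobel
    edge magnitude, local mean/median/entropy filtering), landmark-based
    morphological measurements with a six-stage decision cascade, a compact
    convolutional network classifier trained with categorical cross-entropy
    (SGD or Adam) including an exponential learning-rate range test and a
    confidence-thresholded self-training step, and the standard evaluation
    artifacts (confusion matrix, classification report, per-class one-vs-rest
    accuracy, probability grids).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
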