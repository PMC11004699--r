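Package: agoaelm
Title: Amended Grasshopper Optimization and Extreme Learning Machines for
    Binary Medical Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the grasshopper optimization algorithm (GOA) and an
    amended variant (AGOA) that adds singer-map chaotic streams and
    quasi-opposition-based learning, together with a benchmark validation
    harness, an extreme learning machine (ELM) classifier whose hidden-layer
    weights and biases are tuned by AGOA, an AlexNet-shaped convolutional
    feature extractor with batch normalization for 227x227 images, the full
    confusion-matrix metric suite (accuracy, sensitivity, specificity,
    precision, F1, MCC, PPV, NPV), and synthetic two-class brain-image and
    Gaussian feature-cluster generators for download-free end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
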