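Package: evocnn
Title: Neuroevolution of Convolutional Network Weights for Histopathology
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained convolutional neural network for binary
    classification of histopathology images (benign versus malignant),
    trainable by three optimizers: mini-batch gradient descent, Adam, and a
    real-coded genetic algorithm that evolves the flattened weight vector
    with rank selection, single-point crossover, single-gene mutation and
    elitism. Includes an exact from-scratch forward and backward pass
    (valid convolution, average pooling, ReLU, dense layers, softmax),
    confusion-matrix evaluation (accuracy, error rate, recall, precision,
    F1), BreakHis-style image-folder ingestion with patient-wise
    train/test splitting, and a seeded synthetic two-class texture
    generator so every training and evaluation path runs end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
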