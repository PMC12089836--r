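Package: wmcdetr
Title: Lightweight Wavelet-Convolution Detection Transformer for Tea Pest and
    Disease Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a lightweight DETR-style object detector for tea leaf
    blight and green mirid bug imagery: a wavelet-transform convolution
    (WTConv) ResNet18 backbone, a multiscale multihead self-attention encoder
    block (M2SA-AIFI), and a context-guided spatial feature reconstruction
    neck (CSRFPN), together with a synthetic annotated-image generator, the
    augmentation and split procedure used by the study design it follows,
    COCO-style detection metrics (precision, recall, F1, 101-point mAP), and
    an analytic architecture profiler (parameters, FLOPs, serialized size).
    All components run on the CPU through a small reverse-mode automatic
    differentiation engine with compiled convolution kernels, so the full
    pipeline - fixture generation, training, prediction, evaluation and
    profiling - is exercisable on synthetic images with no external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
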