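Package: shiftclip
Title: Temporal Shift Modules for Video Behavior Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Zero-parameter temporal modeling for short video clips with
    2D convolutional networks. Implements the temporal shift operator and
    its shift/multiply-accumulate decomposition, inserts it into the
    residual branches of four standard backbone families (ResNet50,
    ResNeXt50, ConvNeXt-tiny, DenseNet201) with exact parameter
    accounting, and provides a clip ingestion/split/training/evaluation
    pipeline with Grad-CAM heatmap export. A seeded synthetic-clip
    generator emulates coordinated-displacement behavior (an aggression
    proxy for group-housed livestock) and a playback-direction task that
    isolates temporal modeling, so the full pipeline is exercisable
    end-to-end on one CPU with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
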