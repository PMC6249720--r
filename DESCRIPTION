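Package: ctxseize
Title: Multi-Context Wavelet Feature Fusion for EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizures in annotated EEG recordings by fusing
    three unsupervised feature views of Morlet continuous-wavelet scalograms:
    global principal components over all channels, channel-wise stacked
    denoising autoencoder codes, and temporal embeddings of discretized
    "EEG words" trained with a CBOW objective under hierarchical softmax on a
    Huffman tree. The fused representation feeds a support vector machine
    seizure detector evaluated with precision, recall, F1, accuracy, and
    ROC/PR curves. Includes readers for EDF and single-column ASCII records,
    sliding-window segmentation with ictal labelling, balanced hold-out
    splitting, and a seeded synthetic EEG generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
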