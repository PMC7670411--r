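Package: wsimil
Title: Attention-Based Multiple Instance Learning for Whole-Slide Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of whole-slide histology
    images from slide-level labels only. Implements Otsu tissue
    segmentation and non-overlapping tile extraction, bag construction
    with cutout and mean-pixel regularization, an attention-pooling
    multiple-instance-learning network with mean/max-pooling and
    single-patch baselines, a seeded training engine (Adam, balanced
    sampling, hard-negative mining) with multi-bag slide inference,
    evaluation statistics (Mann-Whitney AUC, percentile-bootstrap
    confidence intervals, PPV/NPV at a threshold, paired DeLong test,
    bootstrap-pooled-variance F-test across cohorts), and an
    attention-weight interpretability workflow (exhaustive slide
    embeddings, k-means with elbow selection, top-attention tile panels,
    attention heatmaps). Includes a seeded synthetic slide-cohort
    generator with known tile-level ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
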