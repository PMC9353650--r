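Package: atsvit
Title: Semi-Supervised Vision Transformer with Adaptive Token Sampling for
    Breast-Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact vision transformer (ViT) classifier for breast
    ultrasound and histopathology images, with attention-based adaptive token
    sampling (ATS): per-block token significance scores are derived from the
    CLS row of the attention matrix and informative tokens are retained by
    inverse transform sampling through the score CDF. Training combines a
    supervised one-vs-all binary cross-entropy loss with two semi-supervised
    consistency losses on unlabeled images - a pseudo-label mean-squared-error
    loss on class probabilities and an Earth Mover's distance loss on
    intermediate token sequences solved by optimal assignment. Includes
    stratified labeled/unlabeled data splitting, seeded image augmentation,
    macro-averaged evaluation metrics for imbalanced classes, a synthetic
    lesion-image generator with ground-truth informative-region masks for
    validating token selection, and PNG image-folder input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
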