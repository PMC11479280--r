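Package: cornstand
Title: Automated Corn Stand Counting from UAS Imagery via Crop-Row-Guided
    Block Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting corn plant stands in high-resolution RGB
    orthomosaics of row-crop fields at early vegetative growth stages.
    Detects crop rows from an HSV vegetation mask, rotates the field so
    rows lie horizontal, auto-labels fixed-size image blocks as corn or
    non-corn using a row-gated green-area criterion, trains a block
    classifier on the auto-generated labels, and counts stands per region
    after probability filtering and intersection-over-union duplicate
    suppression.  Includes a ground-truthed synthetic field generator and
    the standard count-evaluation metrics (precision, recall, F1,
    R-squared, RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    glmnet,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
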