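Package: exdetect
Title: Physical Activity Detection from Continuous Glucose Monitoring and Heart Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting physical activity episodes in people with
    type 1 diabetes from continuous glucose monitoring (CGM) and wearable
    heart-rate (HR) streams. Provides a seeded synthetic cohort simulator,
    readers for Ohio-T1DM-style XML archives and D1namo-style CSV folders,
    the cleaning rules that produce labeled 5-minute series and 24-hour
    analysis blocks, glycemic-dynamics feature extraction over a 15-record
    sliding window (feature sets FS1 and FS2), a suite of 14 classifier
    configurations behind a uniform fit/score/predict contract, and
    confusion-matrix / ROC / AUC evaluation across five train/test use-cases
    including cross-dataset generalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    glmnet,
    rpart,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
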