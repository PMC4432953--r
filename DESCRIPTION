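Package: ishannotate
Title: Automated Annotation of Gene Expression Patterns in Developing
    Mouse Brain ISH Section Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for annotating spatial gene expression patterns in
    stacks of sagittal in situ hybridization (ISH) brain section images.
    Builds brain-wide gene representations two ways: a multi-scale
    bag-of-visual-words over dense gradient-orientation descriptors with
    sagittal-interval aggregation, and layer-tapped convolutional network
    features pooled element-wise across sections. Per-structure binary
    classifiers (L2-regularized logistic regression) predict whether
    expression is detected in each node of a hierarchical brain-structure
    ontology, evaluated by AUC per ontology level. Includes a synthetic
    ISH-stack generator with ground-truth annotations so the whole
    pipeline is testable without atlas data, plus readers/writers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    png,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml,
    glmnet,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
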