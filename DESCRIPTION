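Package: starseg
Title: Segmentation and Tracking of Budding Yeast in Brightfield Time-Lapse
    Images with Polar Active Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tool chain for long-term single-cell analysis of budding yeast
    growing as monolayers in brightfield microscopy. Cells are segmented with
    star-shaped polar active contours ("active rays") whose energy combines
    boundary evidence with interior (surface) evidence, grown from iteratively
    placed seeds and kept or discarded by rank-and-overlap filtering. Frame-to-
    frame tracking solves a linear assignment problem with appearance and
    disappearance costs and a neighbourhood-preserving cost adjustment that is
    robust to collective colony drift. The package also provides benchmark-style
    evaluation metrics (precision, recall and F-measure for segmentation,
    tracking and long-term tracking, with facultative ground-truth elements),
    ground-truth-driven parameter learning by simulated annealing, and a
    synthetic brightfield movie generator with exact ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
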