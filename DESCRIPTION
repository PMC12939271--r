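Package: rootangle
Title: Mesiodistal Root Angulation from Panoramic Tooth Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of mesiodistal tooth root angulation on
    panoramic radiographs from multi-class tooth segmentation label maps.
    Extracts per-tooth instances by connected-component analysis, estimates
    each tooth's long axis from second-order central image moments with an
    orientation-aware exclusion of the apical root segment, and reports the
    angular deviation from the vertical image axis (equivalently, from the
    horizontal film borders used as clinical reference lines). Includes the
    agreement toolbox used to validate such measurements (intraclass
    correlation coefficients with F-based confidence intervals, Bland-Altman
    limits of agreement, Dice overlap, grouped mean absolute errors,
    repeat-acquisition sensitivity summaries) and a synthetic phantom
    generator that produces FDI-labelled dentition maps with known
    ground-truth long-axis angles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    igraph,
    jsonlite,
    png,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
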