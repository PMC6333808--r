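Package: fishbeat
Title: Heart Rate Estimation from Bright-Field Videos of Zebrafish Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated derivation of heart rate from bright-field video
    recordings of microplate wells housing embryonic zebrafish. Embryos are
    segmented from the well image, the heart is located geometrically from
    the Feret diameter and the maximum inscribed (yolk-sac) circle, a
    rectangular region of interest is placed tangent to that circle, and the
    mean-intensity time series it yields is converted to beats per minute by
    segment-wise baseline drift correction followed by discrete Fourier
    transform dominant-frequency estimation. Includes batch processing over
    directories of videos, quality-control renderings, a synthetic phantom
    well generator with known ground truth, and the supporting statistics of
    the assay design (one-way ANOVA power and sample size, Bland-Altman
    method comparison, control-outlier exclusion, and potency slopes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    ggplot2,
    tibble,
    dplyr,
    rlang,
    generics,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
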