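Package: oscillocobb
Title: Oscillogram-Based Cobb Angle Measurement and Lenke Classification
    from Vertebral Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes scoliosis measurements from corner-point landmark
    annotations of spine radiographs. From the four corners of each
    vertebra T1-L5 it derives the 34 endplate tilt angles (the
    "oscillogram"), detects end vertebrae as peaks and troughs of that
    series, and reports Cobb angles for the proximal thoracic, main
    thoracic and thoracolumbar/lumbar regions, T5-T12 kyphosis, per-region
    side-bending residuals, the Lenke curve type (1-6) and the sagittal
    thoracic modifier. Includes a synthetic spine generator with
    analytically known ground truth for all six Lenke curve patterns, and
    inter-rater agreement statistics (mean absolute error, intraclass
    correlation with confidence intervals, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
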