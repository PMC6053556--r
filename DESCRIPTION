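Package: boomr
Title: Acoustic Call-Count Monitoring: Calibration, Individual Counting
    and Cost-Benefit Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating acoustic-recorder-based
    call-count monitoring of cryptic calling birds such as the Australasian
    bittern (Botaurus poiciloptilus). Simulates paired observer/recorder
    call-count campaigns with configurable detection, bearing-noise and
    volume-misclassification models; estimates minimum numbers of calling
    individuals from field-observer bearing/volume/boom criteria and from
    stereo volume-by-direction criteria; calibrates recorder counts against
    observer counts with tie-corrected Spearman rank correlation (Fisher
    z) and through-origin regression; runs an itemized multi-year cost
    model comparing monitoring options; and provides permutation-based
    power analysis for stations-by-occasions call-count designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
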