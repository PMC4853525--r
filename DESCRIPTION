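Package: mediareach
Title: Population Exposure to Alcohol and Tobacco Content in Music Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population-level exposure ("gross impressions") to
    substance content in online music videos by combining three inputs:
    semiquantitative 10-second interval content coding of each video,
    survey-weighted ever-seen reach by age band and gender, and census
    mid-year population counts. Provides survey-weighted proportion
    estimates with design-effect (Kish) confidence intervals, gross and
    per-capita impression estimates with propagated intervals at stratum,
    aggregate and individual-video level, presentation-ready stratified
    exposure tables with an audit trail, and a seeded synthetic-data
    generator emulating the coded-video and survey structure for testing
    and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
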