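Package: emolag
Title: Time-Lagged Cross-Correlation of Public Emotions, Rumors, and Epidemic Case Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infoveillance toolkit linking daily public-emotion signals from
    manually coded social-media comments to online rumor activity and epidemic
    case counts. Implements multi-rater consensus emotion coding with Fleiss'
    kappa interrater reliability, correction of case series across a
    diagnosis-criteria change via a clinical-to-nucleic-acid ratio multiplier,
    construction of aligned log-stabilized daily series with category tallies,
    and a time-lagged Pearson cross-correlation scan with per-lag significance
    and white-noise 95% envelopes. Ships a seeded generator of coupled
    epidemic-emotion-rumor synthetic data so the whole pipeline is testable
    end to end without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    ggplot2,
    readr,
    jsonlite,
    generics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
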