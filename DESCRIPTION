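Package: eegselect
Title: Multi-Objective EEG Channel Selection for Biometric Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An EEG-based biometric pipeline that identifies enrolled subjects
    and rejects intruders, together with a four-objective evolutionary search
    (NSGA-II / NSGA-III) over electrode subsets and classifier parameters.
    Epochs are re-referenced to the common average, decomposed by empirical
    mode decomposition, and summarised per channel by energy and fractal
    features of the two intrinsic mode functions closest to the raw signal.
    A one-class RBF support vector machine authenticates instances and a
    linear multi-class SVM identifies the subject; the genetic search trades
    off channel count against identification accuracy, true acceptance rate
    and true rejection rate. Includes a synthetic EEG generator with known
    informative channels so the whole pipeline can be exercised and the
    channel-selection behaviour verified without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
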