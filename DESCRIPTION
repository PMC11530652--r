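Package: abbrex
Title: Simulation of Abbreviated Text Entry for Augmentative and
    Alternative Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying abbreviation-expansion text entry, a
    paradigm in which users of augmentative and alternative communication
    (AAC) devices type a compressed shorthand of a phrase (word initials,
    optionally mixed with fully or partially spelled keywords) and a
    predictive model proposes full-phrase expansions. The package provides
    the abbreviation algebra (initials-only, complete-keyword, prefix and
    consonant shorthand schemes with punctuation handling), a seeded
    synthetic dialogue-corpus generator, pluggable phrase and fill-mask
    predictors (a configurable oracle and a stupid-backoff n-gram language
    model with constrained beam-search decoding, dialogue-context boosting
    and ARPA interoperability), an ideal-user interaction simulator with
    motor-action accounting and keystroke-saving-rate (KSR) metrics for
    three recovery strategies plus a forward-prediction baseline, and a
    synthesizer of context-shorthand-phrase triplets for model
    fine-tuning. A command-line interface is included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
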