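Package: meiodrive
Title: Population Dynamics and Meiotic Mechanics of X-Linked Sperm-Killing Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic discrete-generation modelling of X-linked meiotic
    drive in populations with limited male mating capacity, including the
    analytic and numeric extinction threshold, phase classification of
    population outcomes, and fixation dynamics of the driving X chromosome.
    Also provides a mechanistic branching model linking cytological
    segregation probabilities during meiosis I and II to spermatid
    composition and realised drive strength, seeded generators for synthetic
    cytological scoring tables and progeny sex counts, and the exact
    count-based statistical tests (two-sided Fisher, exact binomial,
    unpaired t) used to analyse such data, composed into a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    withr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
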