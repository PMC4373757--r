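Package: oaconcord
Title: Paired Differential Expression and Cross-Study Concordance for
    Post-Traumatic Osteoarthritis Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cartilage transcriptomics from paired
    surgical models of post-traumatic osteoarthritis: per-gene paired
    differential expression of operated versus contralateral limbs with
    Benjamini-Hochberg adjustment and probe-to-gene collapsing; exact
    hypergeometric overlap statistics between study gene lists; a
    Monte-Carlo occurrence null for multi-study concordance with its
    Poisson-binomial closed-form oracle; interaction-network hub analysis
    over STRING-style edge tables; pathway over-representation against GMT
    catalogues; and a seeded synthetic-data generator that emulates a
    paired limb design with a decaying differential-expression signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils,
    fgsea
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
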