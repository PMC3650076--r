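Package: vaultgap
Title: Gap Analysis of Global Ex-Situ Crop Collections and Seed Vault Backup
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how completely the world's ex-situ crop
    collections are safety-duplicated in a black-box backup facility such as
    the Svalbard Global Seed Vault. Implements readers for MCPD-style
    passport records, institution registries, WIEWS-like holdings summaries
    and safety-deposit logs; a study-genus selection cascade with an audit
    trail; the FAO State of the World (SoW2) distinct-accession estimator;
    ITPGRFA coverage counting (Annex 1 holdings in Contracting Parties plus
    Article 15 collections, without double counting); per-genus and
    crop-group coverage benchmarks; top-N institutional backup profiles;
    and a seeded synthetic collection-world generator with known ground
    truth for estimator validation and bias experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
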