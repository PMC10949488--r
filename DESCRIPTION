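Package: viralscore
Title: Ensemble Viral-Contig Identification by Rule-Based Score Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the outputs of six viral identification tools
    (VirSorter2, VIBRANT, VirSorter, DeepVirFinder, CheckV, Kaiju) into a
    per-contig viral score via configurable rules and subrules, classifies
    contigs as viral at a score threshold, enumerates and benchmarks all 63
    rule combinations against labeled mock metagenomes (precision, recall,
    Matthews correlation coefficient, prediction overlap), and ships
    generators for labeled mock metagenomes and simulated tool outputs so the
    whole pipeline is testable without running any external tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
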