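Package: regulonkit
Title: Bacterial Regulon Inference from Expression, Operon, Promoter and
    Reporter Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining a bacterial transcription-factor regulon the
    way denitrification studies in Bradyrhizobium japonicum do it:
    replicate-filtered microarray differential expression (detection-call
    filter, Welch t-test, signed fold change), intersection of an
    anoxically-induced gene set with a regulator-mutant differential set,
    operon reconstruction from intergenic distance and gene-name prefixes,
    scanning of promoter fragments for spaced-dyad degenerate RegR boxes,
    transcription-start-site mapping from primer-extension (FLOE) product
    lengths, and quantification of qRT-PCR (Pfaffl) and beta-galactosidase
    reporter (Miller unit) assays. A seeded synthetic-data generator with
    planted truth makes every stage testable without microarray downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
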