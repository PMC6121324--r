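Package: mutmapr
Title: Bulked-Segregant Delta SNP-Index Mapping for Mutagenized Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Gene mapping from two-pool bulked-segregant sequencing of
    EMS-mutagenized crosses, in the MutMap family of methods. Computes
    per-pool SNP indices and their difference (delta SNP index) from
    allelic depths in a two-sample VCF or a plain counts table, smooths
    the statistic with a sliding-window genome scan, calls candidate
    regions, annotates and screens candidate SNPs against gene models,
    checks CAPS (restriction-site) markers, and ships a forward-genetic
    simulator of the pooled cross design so every statistic can be
    validated against its theoretical expectation without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    readr,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    dplyr,
    ggplot2,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
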