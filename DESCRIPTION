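Package: promvar
Title: Promoter SNP Variability Analysis for Gene Groups
Version: 0.1.0
Authors@R:
    person("promvar", "maintainers", email = "promvar@example.org",
           role = c("aut", "cre"))
Description: Whole-genome analysis of single-nucleotide polymorphism (SNP)
    density in promoter regions. Reads UCSC genePred-dialect transcript
    annotation and common-SNP tables (with optional VCF ingestion), applies
    curated-transcript selection, counts SNPs in strand-aware windows
    upstream of transcription or coding-region starts, identifies SNP-rich
    promoters, compares gene groups against the whole-genome background with
    an arcsine-square-root two-proportion test across SNP-count thresholds,
    and scores gene-set overlaps by fold enrichment and the EASE variant of
    the one-sided Fisher exact test. Includes a synthetic annotation/SNP
    generator with a designated elevated-density gene group for calibration
    and power studies, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
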