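Package: cfbackground
Title: Background Somatic Mutation Profiling for Paired cfDNA and White
    Blood Cell Ultra-Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles the background somatic mutation landscape shared by
    circulating cell-free DNA (cfDNA) and white blood cells (WBC) from
    ultra-deep targeted amplicon sequencing. Implements per-read and
    per-base filtering, per-position and per-gene mutant allele frequency
    statistics, paired cfDNA/WBC and technical-replicate correlation,
    hotspot mutation calling with WBC background subtraction, binomial
    limit-of-detection analysis for spike-in dilution series, and a
    deterministic synthetic-data generator with truth tables so the whole
    pipeline can be exercised without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
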