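Package: transhmr
Title: Comparative Hypomethylome Analysis for Transplanted Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hypomethylated regions (HMRs) from CxxC-affinity-capture
    (BioCAP) coverage with a Poisson local-background peak caller, classifies
    them as shared or species-specific between two host nuclear environments
    that carry the same transplanted DNA sequence, and relates species-specific
    methylation states to CpG and GC nucleotide features, repeat age estimated
    from RepeatMasker divergence, transcription start site proximity, and
    species-specific transcription factor occupancy. Ships a synthetic
    composite-genome generator (sequence, methylomes, BioCAP fragment coverage,
    bisulfite counts with conversion spike-ins) so the whole pipeline is
    testable without sequencing data, plus tidy summaries, broom-style tidiers
    and ggplot2 autoplot methods for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
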