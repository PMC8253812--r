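Package: dsbtrace
Title: Genome-Wide Detection of Nuclease-Induced Double-Strand Breaks from
    Tag-Integration Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls CRISPR/Cas-induced double-strand break (DSB) sites from
    tag-integration sequencing experiments, in which a short double-stranded
    oligodeoxynucleotide (Tag) is captured at break sites and read out by
    tag-specific PCR and paired-end sequencing. Provides read demultiplexing
    and Tag filtering, UMI-based PCR-duplicate consolidation, sliding-window
    peak calling with a bidirectional support rule, Smith-Waterman protospacer
    matching for on/off-target classification, cleavage-geometry (blunt versus
    staggered overhang) profiling, a transposon integration-site mode with
    TA-dinucleotide motif enrichment, amplicon deep-sequencing validation
    metrics, and a synthetic-read simulator that provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
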