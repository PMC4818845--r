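Package: alucontact
Title: Transposable-Element Content and Chromatin-Interaction Frequency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links transposable-element (TE) content to Hi-C chromatin-interaction
    frequency inside topological domains. Provides typed readers and writers for the
    interval dialects involved (BED, narrowPeak, RepeatMasker .out, bin-pair and CpG
    tables), stratification of 40-kb bin-pairs into intra- and inter-domain sets with
    data-derived lower and upper frequency thresholds, per-bin-pair TE coverage,
    density and enrichment-score metrics with binned Pearson correlation and Fisher-z
    comparison, origin-partitioned GC content, CpG density and CpG-methylation
    accounting (Alu, SINE/non-Alu, non-SINE), enhancer and active-TSS calling from
    histone-mark peaks with Alu-coverage enrichment tests, and a seeded synthetic-data
    generator that plants the coupling structure the analysis assumes, together with
    an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
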