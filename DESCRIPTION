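Package: methkit
Title: Simulation and Analysis of RRBS, DIP-Seq and Repeat-Family Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for studying genome-wide DNA
    methylation loss between two conditions (wild-type versus
    knockout). Provides a synthetic-data generator that plants
    per-CpG methylation landscapes on a small annotated genome and
    emits RRBS, methylation/hydroxymethylation DNA
    immunoprecipitation (DIP-seq) and RNA-seq reads with full ground
    truth; in-silico MspI digestion and size selection;
    three-letter bisulfite alignment against C-to-T and G-to-A
    converted genomes with per-cytosine methylation calling and
    conversion-rate QC; region-level methylation metrics with
    coverage filters and Fisher-exact differentially methylated
    region detection; gene-body metagene profiling of DIP tag
    densities; two-pass repeat-family read quantification
    (genome annotation then consensus library) with age
    stratification; and median-of-ratios normalisation with a
    negative-binomial differential test and Benjamini-Hochberg
    adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
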