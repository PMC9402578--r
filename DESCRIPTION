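Package: cdsqtl
Title: Coding-Sequence-Focused Splicing QTL Mapping
Version: 0.1.0
Authors@R:
    person("cdsqtl", "developers", email = "cdsqtl@example.org",
           role = c("aut", "cre"))
Description: Maps splicing quantitative trait loci (sQTLs) with an emphasis
    on protein-level consequences. Builds isoform-ratio and
    CDS-integrated-isoform-ratio phenotypes from FPKM matrices, maps
    cis-QTLs with a permutation pass (beta-approximated adjusted p-values)
    and Storey-Tibshirani q-values, scores colocalization with GWAS
    signals via regulatory trait concordance (RTC), characterizes lead
    variant positions on a scaled gene body (Silverman multimodality test)
    and cell-type specificity, evaluates trans-eQTL effects with GSEA on a
    continuous isoform-ratio phenotype, and applies long-read
    candidate-isoform completion filters. Ships a deterministic synthetic
    data generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    limma,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
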