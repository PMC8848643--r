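Package: regsnp
Title: Regulatory SNP Prioritization by Allele-Aware Transcription Factor
    Motif Disruption Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A functional-genomics pipeline for prioritizing candidate
    regulatory risk variants at GWAS loci. Expands index SNPs to linkage
    disequilibrium (LD) proxies via EM haplotype-frequency estimation,
    discovers transcription factor binding motifs from ChIP-Seq peak
    sequences with a ZOOPS (zero-or-one occurrence per sequence) EM
    algorithm, scores allele-specific motif matches with exact
    dynamic-programming p-values, calls binding-disrupting variants with
    an overlap plus significance rule, classifies variants by genomic
    context against gene models, tests allele-specific expression with an
    exact binomial test, and integrates cis-eQTL association evidence
    across datasets. Ships a synthetic-data module that generates every
    input with recorded ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
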