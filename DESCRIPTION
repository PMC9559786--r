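Package: haplotad
Title: Chromatin Architecture Analysis of Disease Risk Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interrogating the chromatin architecture that surrounds
    disease risk haplotypes (linkage-disequilibrium blocks tagged by GWAS
    SNPs). Implements a random-region permutation test for enrichment of
    regulatory-element peaks (histone ChIP-seq, GRO-seq enhancer calls) over
    risk haplotypes with a normal-approximation p-value, CTCF-anchor
    validation of candidate topologically associating domains (TADs), and
    nomination of expressed candidate target genes within retained TADs.
    Ships the juvenile idiopathic arthritis (JIA) risk-haplotype tables as
    machine-readable fixtures, a synthetic-data generator for calibration
    studies, and a single-call pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
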