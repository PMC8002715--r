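Package: phagekit
Title: Comparative Genomics and Infection Analysis Toolkit for Bacteriophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable building blocks for small phage genomics studies:
    k-mer genome signatures compared with the Jensen-Shannon divergence,
    fragment-based average nucleotide identity (ANIb-style) with
    average-linkage ordering of the identity matrix, a domain-count
    lifestyle classifier for actinobacteriophages, minisatellite tandem-array
    detection and copy-number genotyping from spanning sequences,
    strand-aware annotation of single-nucleotide substitutions onto gene
    models, and post-mapping transcriptome arithmetic (TPM, read-origin
    fractions, replicate statistics, fold changes, log2 Pearson
    correlations). Ships deterministic, seeded generators for every input
    class so each stage can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
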