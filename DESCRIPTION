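Package: bioconvr
Title: Unified Interconversion of Bioinformatics File Formats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A native-first framework for converting life-science files
    between formats through one interface: a format and extension registry,
    a converter plugin contract supporting several benchmarkable methods per
    conversion, transitive multi-hop conversion over the format graph,
    transparent gzip/bzip2 compression, and a built-in single- and
    multi-mode benchmarking harness. Supports FASTQ, FASTA, QUAL, CLUSTAL,
    PHYLIP, Stockholm, NEXUS, Newick, GFF3, BED, VCF and SAM natively, and
    BAM through an external-tool contract.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    optparse,
    tools,
    utils,
    stats,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
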