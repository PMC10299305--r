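Package: gtasieve
Title: Screening Particle-Preparation Assemblies for Gene Transfer Agent-Like Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying gene transfer agent (GTA)-like elements in
    coverage-annotated contig sets assembled from virus-like particle
    preparations of intracellular bacteria such as Wolbachia. Implements an
    iterative coverage-stringency convergence procedure that extracts the
    identical high-coverage core shared by two independent preparations,
    six-frame ORF calling with role annotation against a packaged reference
    panel, detection of programmed ribosomal frameshift evidence (slippery
    heptamers, palindromes, short direct and inverted repeats), shared-repeat
    and tandem-repeat analysis, host-genome packaging assessment by k-mer
    mapping, a long-ORF screen for eukaryotic association module (EAM) class
    proteins, in-silico PCR quality control with degenerate primers, and a
    GTA-like versus prophage-like classifier. A synthetic-data generator
    produces particle-prep contig sets with known ground truth so the whole
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    rtracklayer,
    optparse
Config/testthat/edition: 3
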