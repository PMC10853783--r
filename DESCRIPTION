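Package: bacscan
Title: Start-Codon Context Classification, Enrichment Logos and
    Genome-Wide Scanning for Barren AUG Context Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the sequence context of AUG translation
    initiation sites (TIS). Provides a rule-based Kozak classifier
    (optimal/strong/moderate/weak) and a lookup for the eight barren AUG
    context sequences (BACS) that disfavour translation across species;
    normalisation and rank-based statistics for dual-luciferase reporter
    assays (per-plate Renilla control standardisation, top/bottom percentile
    splits, fold changes with Wilcoxon rank-sum tests); position-probability
    and enrichment/depletion matrices for sequence logos with a reproducible
    degenerate-consensus caller; an anchored IUPAC motif engine (parsing,
    expansion, matching, regex emission); strand-aware extraction of start
    codon contexts from genome FASTA plus GFF3 annotation with pattern and
    exact-sequence scanning and gene-ontology binning; and a synthetic
    dual-luciferase assay and toy-genome generator so the whole pipeline is
    testable from simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'bacscan-package.R'
    'motif.R'
    'contexts.R'
    'expression.R'
    'synthetic.R'
    'genome-scan.R'
    'logo.R'
    'cli.R'
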