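Package: mitoCR
Title: Annotation and Typing of the Mitochondrial Control Region in Lacertid Lizards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of vertebrate mitochondrial
    genomes with a focus on the control region (CR) of lacertid lizards.
    Reads annotated mitogenomes from GenBank flat files or plain FASTA,
    extracts the control region from the tRNA-Pro/tRNA-Phe boundary, scans
    gene overlaps and the light-strand replication origin motif, locates the
    conserved control-region elements (TAS1, TAS2, CSB1, CSB2, CSB3) by
    fuzzy matching against the Lacerta dugesii reference motifs, renders and
    classifies dot-notation variants against shipped variant tables, detects
    tandem-repeat arrays, and classifies control regions into five general
    types and twenty-one subtypes via an editable rule table. Accessory
    statistics include base-composition skews, codon usage (counts, codons
    per thousand, RSCU), uncorrected p-distance, and Nei-Gojobori (1986)
    dN/dS with Jukes-Cantor correction. Seeded generators produce synthetic
    mitogenomes, control regions, and codon alignments with machine-checkable
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'mitoCR-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'genbank-io.R'
    'control-region.R'
    'overlaps.R'
    'composition.R'
    'elements.R'
    'repeats.R'
    'typing.R'
    'dnds.R'
    'synthetic.R'
    'reports.R'
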