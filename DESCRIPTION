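Package: torsionCouple
Title: Torsional Coupling of Adjacent Genes Through
    Transcription-Generated DNA Supercoiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative modelling of the mechanical coupling between
    neighbouring genes mediated by DNA supercoiling. Transcription generates
    positive torsional stress ahead of the elongating polymerase and negative
    stress behind it; the package computes the resulting time-averaged
    superhelical-density field along the genome, the supercoiling-dependent
    opening free energy of promoter sequences (a single-bubble
    stress-induced duplex destabilization calculation with a sigmoidal fit),
    and the thermodynamic transcription rate at an effective temperature.
    These ingredients are combined into a self-consistent fixed-point solver
    for pairs (or chains) of coupled genes, producing orientation x distance
    x basal-supercoiling fold-change diagrams. A genomics pipeline selects
    "torsionally isolated" neighbour-gene pairs from a GFF3/GTF annotation,
    classifies their orientation (divergent, convergent, tandem), and
    computes binned expression and co-expression statistics from a genes x
    experiments matrix. Synthetic annotation, expression and promoter
    sequence generators support fully reproducible desk-scale analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
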