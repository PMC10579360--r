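Package: MimicryScan
Title: Molecular Mimicry Screening Between a Microbial Protein and Human
    Autoimmune Epitopes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A screening pipeline for candidate molecular mimicry between a
    microbial target protein (microbial transglutaminase from Streptomyces
    mobaraensis is the motivating case) and catalogs of human autoimmune
    epitopes. Implements Waterman-Eggert local pairwise alignment with affine
    gaps and declumped sub-optimal alignments, identity/similarity statistics
    under BLOSUM62, an identity/length mimicry cutoff, an HLA-I/II IC50
    immunogenicity filter consuming precomputed binding predictions, an
    intersection with ELISA cross-reactive antigens, and the ELISA
    background-cutoff (mean + k*SD) reactivity analysis with duplicate-well
    quality control. Ships synthetic-data generators (planted-homology epitope
    catalogs, binding tables, optical-density panels) so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: SequenceMatching, Alignment, Proteomics, ImmunoOncology
RoxygenNote: 7.3.3
Collate: 
    'MimicryScan-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'matrix.R'
    'align.R'
    'io.R'
    'elisa.R'
    'screen.R'
    'synthetic.R'
    'pipeline.R'
    'table1.R'
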