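Package: intronevo
Title: Intron Size Evolution Across a Species Phylogeny
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of spliceosomal intron
    lengths across a clade of species: intron cataloguing from genome
    annotation, detection of bimodal log-scale size distributions,
    alignment-based intron orthology using transcripts with sticky intron
    meta-characters, Kimura two-parameter distances and neighbour-joining
    trees from exon alignments, Sankoff maximum-parsimony reconstruction
    of discretised ancestral intron sizes, cross-species size-association
    statistics (mutual information with permutation nulls, quantile
    cross-prediction, size-partitioned correlations), nested hypergeometric
    depletion scans of functional terms, and detection of conserved intron
    sequence with a recursive local-alignment scan calibrated against a
    search-space null model. Includes a synthetic multi-species cohort
    generator with known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
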