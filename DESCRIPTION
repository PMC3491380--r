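Package: cynoseq
Title: Whole-Genome Resequencing Analysis for a Diploid Macaque Genome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing whole-genome resequencing of a diploid
    primate genome against a draft reference assembly: a Bayesian diploid
    genotype caller for pileup evidence with assembly-quality-stratified
    filtering, variant-effect annotation under site-class priority rules,
    multi-genome comparative SNV analysis, within- and between-species
    population-genetic statistics (nucleotide diversity, d_xy,
    nonsynonymous/synonymous contrasts), small-indel and mate-pair
    structural-variant detection including inversion window scans, and
    demographic inference from a single diploid genome with a discretised
    sequentially-Markovian-coalescent hidden Markov model fitted by EM.
    A synthetic-data generator with known truth (sequential-coalescent
    TMRCA tracts, pileups, mate-pair libraries) supports end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'genotyping.R'
    'simulate.R'
    'simulate_evidence.R'
    'genes.R'
    'comparative.R'
    'popgen.R'
    'structural.R'
    'demography.R'
    'io.R'
    'report.R'
    'RcppExports.R'
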