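Package: txkinetics
Title: Stochastic Kinetic Modeling of RNA Polymerase II Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A global kinetic model of the yeast RNA polymerase II
    transcription cycle. Implements an exact (Gillespie) stochastic
    simulator of a discretized model gene with hard-core exclusion,
    an exact continuous-time Markov chain oracle for small architectures,
    ensemble grid-search fitting of unknown transcription-cycle rates to
    region-binned occupancy profiles using cosine similarity, perturbation
    modeling of preinitiation-complex components, and the genomic-signal
    computations (region binning, metagene and metasite profiles, CPM
    normalization, background subtraction) used to derive occupancy
    vectors from coverage tracks. Includes synthetic-data generators
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
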