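Package: famevol
Title: Gene Family Evolution: Duplication Mapping, Ks Dating, Codon
    Selection Models and Functional Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the expansion and divergence of plant
    transcription-factor gene families, built around the WRKY family as the
    motivating case.  Detects WRKY domains and zinc-finger patterns and
    assigns proteins to the classical group I / II(a-e) / III scheme;
    classifies duplicate gene origins as tandem, segmental or dispersed from
    chromosome coordinates and flanking-gene anchors; estimates Ka/Ks by the
    Nei-Gojobori method and dates duplication blocks with a synonymous
    molecular clock; fits GY94 codon substitution models (M0, M3, M7, M8 and
    branch-site model A) by maximum likelihood with likelihood-ratio tests
    and empirical-Bayes site identification; estimates Type-I and Type-II
    functional divergence between paralogous clusters; and characterizes
    tissue expression breadth and promoter cis-element content.  A full set
    of synthetic-data generators (trees, codon alignments, genome layouts
    with planted tandem arrays and segmental blocks, expression atlases,
    promoters) provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
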