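Package: paircn
Title: Joint Copy Number Calling and Pairwise Evolutionary Distances for
    Single-Cell Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers somatic copy number profiles from binned single-cell
    whole-genome read depth by explicitly modelling the shared evolutionary
    history of pairs of tumor cells. A continuous-time Markov chain over the
    copy numbers of adjacent genomic bins is extended to a two-lineage
    process on a three-branch tree, embedded in a hidden Markov model with
    negative-binomial emissions calibrated on matched diploid cells. The
    package fits per-cell models, estimates pairwise tree branch lengths by
    maximum likelihood, decodes joint copy number profiles with the Viterbi
    algorithm, summarises them into consensus profiles, and uses the summed
    divergent branch lengths as a distance metric for neighbor-joining
    phylogeny reconstruction. A line-segment tumor-evolution simulator and
    accuracy metrics (profile sum of squared errors, breakpoint distance and
    inflation) support validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    ape,
    phangorn,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
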