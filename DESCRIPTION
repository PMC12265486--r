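Package: j1balance
Title: Universal Tree Balance Index J1 for Rooted Trees with Arbitrary
    Degrees and Node Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the universal tree balance index J1 -- a weighted mean of
    per-node normalized Shannon entropy balance scores -- for rooted trees with
    arbitrary outdegrees and non-negative node sizes, together with the Sackin
    and generalized Sackin (weighted path length) indices. Provides exact shape
    enumeration and exact expected values of J1 under the Yule and uniform
    (PDA) null models, closed-form first- and second-order approximations and
    their Jensen gaps, seeded Yule and uniform tree samplers, Huffman
    construction of the maximally balanced bifurcating leafy tree for given
    leaf sizes, and a closed-form extremal analysis of minimally balanced
    broom trees. Trees are read and written in Newick format with NHX-style
    per-node size annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
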