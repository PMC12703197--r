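Package: convarfinder
Title: Detection and Classification of Convergent Sequence Variants in
    Polyphyletic Species Groups
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scans multi-species sequence alignments for variants that are
    mutually exclusive between a polyphyletic target group and a background
    group at the amino acid, codon, and nucleotide levels; classifies each
    variant into four convergence/divergence types; traces codon and
    nucleotide origins (single nucleotide variants versus complex
    nonexclusive nucleotide variants); verifies evolutionary direction by
    ancestral state reconstruction on a fixed rooted tree; enumerates
    control species combinations drawn from independent lineages; and
    relates variant counts to phylogenetic branch features (products of
    origin and terminal branch lengths, summed branch and node distances)
    with rank correlation, linear regression, Bonferroni outlier testing,
    hypergeometric gene-set overlap, and substitution-score principal
    component analysis. Includes a tree-consistent alignment simulator with
    planted variants so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
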