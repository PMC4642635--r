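Package: hapshare
Title: Haplotype-Sharing Measures of Genomic Relatedness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes two haplotype-sharing measures of genomic relatedness
    defined on segment multisets induced by an acyclic probabilistic finite
    automaton (APFA): the intersect measure B, which estimates the fraction
    of shared genome between individuals, and the product measure C, which
    equals twice the identity-by-state coefficient of coancestry off the
    diagonal and one plus the identity-by-state inbreeding coefficient on
    the diagonal.  Also provides the pedigree numerator relationship matrix
    A, vanRaden's marker-based G, a hybrid expected/realized relationship
    algorithm for partially genotyped pedigrees, a covariance-conditioning
    operator that replaces the marginal covariance of a subgroup while
    preserving conditional covariances, a gene-drop meiosis simulator on
    segment sequences, and principal-coordinates embedding of the
    -log(b) haplotype-sharing distance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
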