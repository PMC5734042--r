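Package: orfrescue
Title: Pseudogene Lesion Detection, Ancestral ORF Repair, and Enzyme
    Rescue Analytics for Subtelomeric Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing pseudogenizing lesions in duplicated gene
    families and for testing whether a minimal single-base edit resurrects
    an ancestral full-length open reading frame. Implements global pairwise
    alignment statistics (percent identity and BLOSUM-positive percent
    similarity), an exhaustive single-base repair scan (substitution,
    insertion, deletion) with a four-criterion ancestral-ORF audit,
    catalytic-residue mapping through protein alignment, alignment-free
    k-mer distances with neighbor-joining trees, ortholog hit filtering,
    Michaelis-Menten kinetics fitting for resurrected enzymes, and a
    synthetic gene-family generator with planted lesions and known ground
    truth. Motivated by the aryl-alcohol dehydrogenase (AAD) family of
    Saccharomyces cerevisiae, a subtelomeric aldo-keto reductase family in
    which frameshifts, premature stops, catalytic missense mutations and
    5' deletions have eroded most copies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
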