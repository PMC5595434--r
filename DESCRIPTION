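Package: ibdmapr
Title: Identity-by-Descent Mapping of Recessive Disease Loci in Founder Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping recessive disease loci through identity-by-descent
    (IBD) sharing in bottlenecked founder populations. Implements a word-hash
    IBD segment detector for phased haplotypes, mask and sharing-depth quality
    filters, connected-component clustering of overlapping IBD tracts into
    haplotypic "cliques" with 0/1/2 dosage encoding, recessive-model trait
    association with Bonferroni control and genomic-control lambda, a
    phenome-wide association scan of rare carrier predictors against binary
    diagnosis codes with maximum-likelihood, Firth-penalized and
    saddlepoint-approximation logistic engines, IBD tract-length-spectrum
    estimation of historical effective population size, an integrated
    haplotype score (iHS) selection scan, and a forward Wright-Fisher
    founder-population simulator with exact ground-truth IBD for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
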