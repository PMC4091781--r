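Package: scClonality
Title: Single-Cell Validation of Tumor Clonal Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing clonal-architecture models inferred from
    bulk tumor sequencing against targeted single-cell genotypes.
    Simulates clonal hierarchies and single-cell read counts with
    whole-genome-amplification artifacts (allelic dropout, locus dropout,
    overdispersed coverage), calls genotypes with a coverage gate,
    classifies sorted samples as clonally pure or mixed with a binomial
    likelihood-ratio test, assigns cells to clones, separates allelic
    dropout from cryptic substructure, detects mutually exclusive variant
    sets marking evolutionary branch points, and reconstructs cell
    phylogenies by neighbor joining with nonparametric bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, ape
Suggests: testthat (>= 3.0.0), phangorn, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
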