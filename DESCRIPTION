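Package: DCJAliquot
Title: Genome Aliquoting by Double-Cut-and-Join Distance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a perfectly duplicated ancestor of a rearranged
    r-way duplicated genome (the genome aliquoting problem, genome halving
    for r = 2) while heuristically minimising the double-cut-and-join (DCJ)
    distance.  Provides signed multichromosomal gene-order genomes with
    gene-family copy labels, partial and contracted partial graphs, an exact
    labeled DCJ distance, a disjoint-path engine with per-pair cycle scoring
    for weak-adjacency inference, a whole-genome-duplication simulator with
    random DCJ rearrangements, and an evaluation pipeline comparing inferred
    and simulated distances.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, ComparativeGenomics, Phylogenetics
RoxygenNote: 7.3.3
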