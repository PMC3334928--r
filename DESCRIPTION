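Package: phylodegen
Title: Codon-Aware Recoding, Deliberately Incomplete Supermatrices, and
    Desk-Scale Partitioned Likelihood Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain used in multi-gene molecular
    phylogenetics of protein-coding nuclear genes: degen1 codon recoding
    (full degeneration of synonymously variable sites using IUPAC ambiguity
    codes), construction of the non-synonymous nt1+nt2 versus potentially
    synonymous nt1+nt3 character partitions via leucine/arginine-aware
    first-position filtering, supermatrix concatenation with deliberately
    incomplete taxon-by-gene sampling designs and exclusion masks,
    desk-scale partitioned maximum-likelihood inference under GTR+gamma+I
    with stepwise-addition starting trees, NNI hill climbing and
    nonparametric bootstrap, cross-analysis node-support comparison
    including a missing-data-artifact check, and diet-breadth
    (oligophagy/polyphagy) classification from host-association record
    tables.  A synthetic-data module simulates codon alignments on known
    trees with lineage-specific synonymous-site compositional shifts,
    block-missing gene sampling designs, and host-record tables with known
    diet labels, so the whole pipeline can be exercised with known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
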