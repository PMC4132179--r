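Package: chiscreen
Title: Analysis of Complex Heterozygosity Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing complex heterozygosity (CHI) genetic
    interaction screens in which point-mutant query alleles of a single
    gene are crossed against a panel of deletion alleles and scored for
    digenic growth defects. Provides the interaction-matrix data model
    with severity scores and weight reversal, degree statistics and
    degree-feature correlations, replicate-based gold standards with
    precision and recall, two-way hierarchical clustering of interaction
    profiles (uncentered Pearson similarity, average linkage) with
    Cluster 3.0 / Java TreeView compatible export, mapping of mutated
    residues onto monomer and filament structures with minimum
    alpha-carbon distances in stacked and backed subunit configurations,
    Mantel-style permutation tests relating profile similarity to
    structural distance, and a synthetic-data generator that plants
    allele clusters on an idealised helical filament so that the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
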