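Package: habitatscan
Title: Detecting Recent Marine-Freshwater Habitat Transitions from 16S Amplicon Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and rank recent transitions of microbial
    lineages between marine and freshwater habitats from aligned 16S rRNA
    V4 amplicon data. Implements one-gap pairwise sequence distances and
    farthest-neighbor (complete-linkage) clustering at every identity
    cutoff on a fine grid; the cross-habitat shared-identity scan statistic
    (the highest identity threshold at which a marine and a freshwater
    sample still share a sequence cluster); unweighted and weighted UniFrac
    with pooled-habitat group distances, independent-swap null ensembles,
    one-sample z tests and permutation PerMANOVA; shared-taxon reports,
    accumulation curves and habitat fold-enrichment summaries; a binomial
    detection-limit model for rare populations; and a synthetic community
    generator with controllable habitat-transition history so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
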