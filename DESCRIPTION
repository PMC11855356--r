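Package: phydisc
Title: Coalescent Simulation and Introgression Detection for
    Cyto-Nuclear Discordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to distinguish incomplete lineage sorting (ILS) from
    introgression as causes of gene-tree/species-tree and cyto-nuclear
    (plastid versus nuclear) phylogenetic discordance. Provides a
    multispecies-coalescent gene-tree simulator on species trees and on
    networks with inheritance probabilities, Jukes-Cantor sequence
    simulation along gene trees, Robinson-Foulds distance distributions
    with a Mann-Whitney rank test, per-node gene-tree concordance
    mapping, site-pattern invariants hybridization detection with a
    moment estimator of the inheritance probability gamma and a
    bootstrap Z-test, and a QuIBL-style exponential-mixture EM on
    triplet internal branch lengths with BIC model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
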