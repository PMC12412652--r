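Package: bh3forge
Title: Computational Design and Assay Analytics for BH3-Groove Binders of BAK and BAX
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the computational pipeline behind
    BH3-mimetic binder design against the proapoptotic effectors BAK and BAX:
    motif-grafted scaffold docking with geometric and clash tolerances,
    Monte Carlo interface sequence design under a simplified pairwise
    potential, design filtering (predicted binding energy, shape
    complementarity, buried unsatisfied polar atoms, peptide-bond omega
    geometry), directed-evolution analytics (per-mutation enrichment from
    sorted pools, dual independent-enrichment selection, degenerate-codon
    combinatorial library design under a diversity cap), 1:1 biolayer
    interferometry kinetic fitting, and an equilibrium concentration-threshold
    model of binder-induced pore activation and inhibition with
    four-parameter-logistic dose-response analysis. Synthetic-data generators
    with known ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
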