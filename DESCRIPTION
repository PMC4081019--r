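Package: ubscape
Title: Coarse-Grained Binding and Functional Landscapes of Ubiquitin Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-bead coarse-grained simulator and analysis stack for the
    conformational landscapes of dimeric ubiquitin (diUb) chains. Interactions
    within each ubiquitin unit are structure-based (Go-like), while
    inter-monomer interactions combine Debye-Hueckel screened electrostatics
    with a Miyazawa-Jernigan-derived hydrophobic potential. The package builds
    the coarse-grained model from a monomer PDB structure, constructs any of
    the eight polyubiquitin linkage topologies (M1 and the seven lysines) or
    the free unlinked pair, samples with Langevin dynamics over independent
    replicas, and analyses the resulting ensembles: order parameters,
    free-energy surfaces, interfacial contact profiles and symmetry scores,
    open/closed/compact state populations, entropy-enthalpy decomposition,
    dissociation-constant estimation and three-state reconciliation of
    two-state readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
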