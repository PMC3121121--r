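Package: dbac
Title: Hot-Spot Residue Prediction from Deeply Buried Atomic Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein binding hot-spot residues from the burial
    level of atoms, residues and atomic contacts. Burial level is a graph
    descriptor: atoms are nodes of a Voronoi/Delaunay-constrained atomic
    contact graph (buried crystallographic waters included), exposed atoms are
    anchored to a pseudo solvent node, and an atom's burial level is its
    shortest-path distance to that node minus one. Interfacial atomic contacts
    directly broken by alanine substitution are typed as charged-pair,
    donor-acceptor or other, counted per burial band, and fed with the residue
    burial level to a radial-basis support vector machine evaluated under a
    nested leave-one-out protocol. Includes a Shrake-Rupley solvent accessible
    surface area implementation, deterministic synthetic structure generators
    for end-to-end validation, and evaluation metrics with Mann-Whitney
    significance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    igraph,
    RANN,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
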