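Package: gqwater
Title: Water-Mediated Ligand Binding in G-Quadruplex Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of structured water molecules that mediate small-molecule
    binding to G-quadruplex DNA in crystal structures. Detects hydrogen bonds
    under configurable geometric criteria (donor-acceptor distance and angular
    deviation from ideality), builds ligand-water-DNA contact networks and
    enumerates bridging water chains, classifies hydration shells and water
    clusters, converts crystallographic B factors to root-mean-square
    displacements, and identifies conserved water positions between structures
    by rigid-body superposition of G-quartets. Includes a fully ground-truthed
    synthetic scene generator for end-to-end validation, and packaged
    hydrogen-bond contact tables for two quadruplex-ligand complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
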