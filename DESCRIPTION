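Package: abitope
Title: Antigen-Antibody Interface and Epitope Analysis from Macromolecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural analysis of antigen-antibody and receptor-ligand
    interfaces from PDB/mmCIF coordinate files. Implements Shrake-Rupley
    solvent-accessible surface area with a deterministic spiral point
    lattice, buried-surface-area and per-chain contribution computation,
    geometric typing of interface contacts (hydrogen bonds, salt bridges,
    van der Waals contacts, water-mediated bridges), epitope extraction
    and cross-complex comparison in a common antigen frame, Fab
    elbow-swing and loop-plasticity quantification, structure-based
    alignment of homologous antigens with side-chain graft steric-clash
    scanning, and N-glycosylation sequon mapping. Ships a synthetic
    fixture generator with analytically known ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
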