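Package: mfccmbe
Title: Fragment-Based Protein-Ligand Interaction Energies with MFCC and
    Many-Body Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the molecular fractionation with conjugate caps (MFCC)
    partitioning of proteins into single amino acid fragments with ACE/NME
    capping, disulfide methyl-sulfide caps, and the MFCC-MBE(2) many-body
    upgrade for total energies and protein-ligand interaction energies.
    Builds the signed subsystem ledgers of both schemes, applies a
    distance-cutoff screen to three-body (fragment/cap plus ligand) terms,
    and evaluates the resulting energy expressions with pluggable backends:
    exactly verifiable analytic pair and three-body potentials, or scalar
    energies imported from an external quantum-chemistry engine through a
    plain-text geometry manifest.  A fixture module generates idealized
    polypeptides, protein-ligand complexes and bead-chain systems so the
    whole algebra is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
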