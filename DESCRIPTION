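Package: cgdna
Title: Coarse-Grained DNA and Protein-DNA Simulation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a sequence-aware coarse-grained force field for
    double-stranded DNA with two or three interaction sites per nucleotide
    (charged sugar-phosphate backbone bead, base bead, and optionally a small
    hydrogen-bonding dummy bead for directional base pairing), together with a
    one-bead-per-residue hydropathy-scale (HPS) protein model and the
    protein-DNA cross-interactions that couple the two. Provides topology
    builders with Watson-Crick pair classification, an ideal B-form DNA
    coordinate generator, all bonded and nonbonded energy terms (harmonic
    bonds, cosine-squared angles, 12-10 stacking and hydrogen bonding,
    Weeks-Chandler-Andersen excluded volume, Debye-Hueckel screened
    electrostatics, Ashbaugh-Hatch HPS pair potential) with analytic forces,
    a BAOAB Langevin integrator, temperature replica exchange, and harmonic
    centre-of-mass umbrella sampling. Analysis routines cover duplex
    hybridization classification, melting curves and heat-capacity melting
    temperatures, helical structure (base rise, duplex width, base pairs per
    turn, groove widths), WHAM unbiasing of umbrella windows into radial
    potentials of mean force, dissociation constants from PMF volume
    integrals, and intermolecular contact maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
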