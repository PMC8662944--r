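Package: qrlite
Title: Desk-Scale Quantum Refinement of Crystal Structures with Continuum Solvation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint refinement of a selected region ("system 1") of a
    macromolecular crystal structure against a quantum-chemical (or
    classical surrogate) energy, molecular-mechanics restraints and a
    crystallographic amplitude target, extended with a COSMO
    conductor-like continuum-solvation term. Includes independent-atom
    structure factors with isotropic displacement parameters,
    least-squares and maximum-likelihood amplitude targets with analytic
    gradients, per-residue real-space difference-density Z scores,
    strain energies, dual-conformation refinement with fixed
    occupancies, dielectric-constant scans, and a deterministic
    toy-crystal generator for validation.
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
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
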