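Package: cosmosol
Title: Conductor-Like Screening Model Engine with GEPOL Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A standalone engine for the conductor-like screening model
    (COSMO) of continuum solvation. Builds van der Waals and approximate
    solvent-excluding-surface cavities by GEPOL93 tessellation of atomic
    spheres (pentakisdodecahedron meshes at 60/240/960 tesserae per sphere,
    auxiliary filler spheres, segment merging), assembles the segment
    Coulomb matrix in the Klamt-Schuurmann point-charge or York-Karplus
    Gaussian form, solves the conductor boundary condition 0 = Phi + A q,
    applies dielectric scaling, corrects outlying charge by scaling factors
    or Lagrange multipliers with consistently corrected potentials, and
    reports dielectric energies, Turbomole-style COSMO files and
    sigma-profiles. Solutes are classical charge models (point nuclei plus
    spherical Gaussian electron clouds) so the whole pipeline is testable
    without a quantum-chemistry backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
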