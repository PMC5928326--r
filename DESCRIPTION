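Package: aromring
Title: Force-Field Parameterization and Hydration Analysis for Aromatic Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for GROMOS-style force-field parameterization and
    validation of small aromatic molecules: dipole-constrained partial-charge
    fitting under charge-group constraints, periodic dihedral-potential
    fitting to quantum-mechanical torsion scans, liquid-phase thermodynamic
    observables (density, enthalpy of vaporization, thermal expansion, heat
    capacity, isothermal compressibility, dielectric constant, energy-drift
    quality control) from simulation time series, thermodynamic-integration
    solvation free energies, and a hydrogen-bond / solvation-shell analysis
    battery (occupancy, residence times, Eyring breakage free energies,
    radial distribution functions, coordination numbers, water orientation).
    Includes deterministic synthetic-data generators with known ground truth
    for every estimator. Readers and writers for GRO/XYZ coordinates, an
    ITP topology subset, and XVG-like observable tables are provided; the
    quantum-chemistry and molecular-dynamics engines themselves are out of
    scope and enter only through their output files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
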