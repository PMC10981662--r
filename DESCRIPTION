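Package: memfis
Title: Self-Consistent Field Theory of Lipid Membrane Fission Intermediates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-field molecular theory of lipid bilayers, membrane
    nanotubes and their fission intermediates. Lipids are modelled as
    Gaussian AB diblock chains in a short homopolymer solvent and solved by
    self-consistent field theory (SCFT) in planar, cylindrical radial,
    axisymmetric and coarse Cartesian geometries in the semi-grand canonical
    ensemble, where an exchange chemical potential controls membrane tension.
    Membrane observables (bilayer thickness, tension, tube radius, bending
    rigidity) are extracted from converged states and calibrated to physical
    units. The simplified string method relaxes strings of density
    configurations to minimum free-energy paths between membrane topologies
    (tubes, hemifusion stalks, pores, worm-like micelles), and a fluorometry
    module implements nanotube radius and lamellarity quantification from
    fluorescence line scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
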