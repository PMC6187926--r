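Package: aggtrap
Title: Flow and Nutrient Microenvironment of Multicellular Aggregates in
    Microfluidic Traps
Version: 0.1.0
Authors@R:
    person("aggtrap", "developers", email = "aggtrap@example.org",
           role = c("aut", "cre"))
Description: Steady-state simulator for the microenvironment of toroidal and
    spheroidal multicellular aggregates held in microfluidic traps (U-shaped
    barriers or microwells).  Builds a voxelized, region-labelled description
    of the device from signed-distance geometry, solves low-Reynolds
    incompressible flow of the culture medium on a staggered finite-volume
    grid, and solves conjugate species transport (advection-diffusion in the
    medium, pure diffusion in the oxygen-permeable elastomer, diffusion with
    Michaelis-Menten consumption in the tissue) with solubility-partition
    jump conditions at material interfaces.  Reports the quantities that
    matter for aggregate culture: average and minimum oxygen and glucose
    concentration in the tissue, hypoxic volume fraction, and the maximum
    shear stress on the aggregate surface.  Includes closed-form oracles
    (constant-rate sphere profile, hypoxic-radius calculator, two-layer slab,
    a one-dimensional Michaelis-Menten radial solver) and synthetic fixture
    generators used for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
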