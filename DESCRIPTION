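Package: nmrflex
Title: Integrative NMR/SAXS/ITC Modeling of Flexible Multidomain
    Protein-RNA Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize multidomain RNA-binding proteins with
    flexible interdomain linkers and to build restraint-driven structural
    models of their RNA complexes. Implements chemical shift perturbation
    (CSP) mapping and threshold-based ambiguous restraint generation, 15N
    R1/R1rho relaxation fitting with offset correction and rotational
    correlation time (tauc) analysis, paramagnetic relaxation enhancement
    (PRE) intensity-ratio conversion to flat-bottom distance restraints via
    the Solomon-Bloembergen relation, flexible-linker conformer sampling
    with rigid domains under a steric acceptance rule, Metropolis
    simulated-annealing refinement against PRE and ambiguous CSP restraints,
    SAXS analysis (Debye curves, Guinier fits, pair-distance distributions,
    chi-square model/data fitting), and one-site ITC isotherm simulation and
    fitting with binding thermodynamics. A synthetic-data module generates
    toy multidomain protein-RNA systems with simulated observables for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
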