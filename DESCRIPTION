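Package: IonTrackDamage
Title: Track-Structure Simulation and Scoring of DNA Damage by Light Ions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates DNA damage induction by light ions (H, He, C, N, O, Ne;
    ~0.01-256 MeV/u) in a spherical cell-nucleus target. Ion interaction data
    are obtained by a generalized Barkas effective-charge scaling of a packaged
    hydrogen-in-water baseline; ions are transported event by event with a
    parametric secondary-electron kernel; linear energy transfer is scored from
    dose and fluence, nucleus-averaged, restricted to a spherical cap for
    stopping ions, or locally in 200-nm slabs. Energy deposits are superposed
    on a coarse voxelized chromatin model to induce strand breaks (direct
    5-37.5 eV ramp, a hydroxyl-radical surrogate for indirect action, and a 1%
    single- to double-strand-break conversion), and the resulting lesions are
    classified into double-strand breaks, DSB clusters, DSB sites,
    multiplicities and single-track DNA fragment-size spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
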