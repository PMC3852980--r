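Package: freesolvent
Title: Free-Solvent Thermodynamics of Concentrated Macromolecule Solutions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts osmotic pressure and the activity coefficient of
    free-solvent for concentrated globular-protein and small-solute aqueous
    solutions using only independently measurable physical quantities:
    solution composition, hydration derived from solvent-accessible surface
    area (SASA), and protein-ion binding.  The protein together with its
    bound water and ions is treated as a single hydrated macromolecule, so
    the remaining (free) solvent behaves ideally.  Includes the inverse
    operations (back-calculating activity coefficients from membrane
    osmometry data), bounded nonlinear least-squares regression of hydration
    and ion-binding parameters from osmotic-pressure datasets, and a seeded
    synthetic osmometry generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
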