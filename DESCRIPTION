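Package: MicelleMetrics
Title: Shape, Scattering, Surface and Ionic-Structure Analysis of Peptoid Micelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural characterization of self-assembled micelles of
    sequence-defined charged peptoid block copolymers from molecular
    configurations and trajectories. Provides mass- and scattering-length-
    weighted gyration-tensor analysis (radius of gyration, eigenvalue spectra,
    asphericity, shape parameter), Shrake-Rupley solvent-accessible surface
    area with a rolling probe, neutron-weighted radial distribution functions
    and the static structure factor with Guinier-regime radius extraction,
    and ionic-structure statistics (sodium and water coordination of
    carboxylate groups, interchain carboxylate neighbor distances, salt-bridge
    and counterion-condensation fractions). A synthetic micelle generator with
    planted structural ground truth and ideal geometric bodies makes every
    analysis stage testable without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'MicelleMetrics-package.R'
    'elements.R'
    'atoms.R'
    'pbc.R'
    'select.R'
    'gyration.R'
    'io.R'
    'ions.R'
    'reporting.R'
    'scattering.R'
    'sasa.R'
    'synthetic.R'
    'pipeline.R'
    'systems.R'
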