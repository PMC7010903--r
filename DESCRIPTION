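Package: celldose
Title: Cellular Dosimetry for Lutetium-177 Radiopharmaceutical In Vitro Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monte Carlo cellular S values and MIRD-formalism absorbed doses to
    the cell nucleus for in vitro experiments with Lu-177 labelled
    radiopharmaceuticals (e.g. 177Lu-DOTATATE on U2OS+SST2 monolayers).
    Implements a straight-line continuous-slowing-down (CSDA) electron
    transport engine over spherical, truncated-cone and polygonal-mesh cell
    geometries with cytoplasm, membrane, nucleus and Golgi compartments;
    self-dose and cross-dose in hexagonal monolayers and growing colonies;
    time-activity curve fitting and per-interval cumulated activities over a
    4-h uptake plus 6-day colony-forming follow-up; linear and
    linear-quadratic clonogenic dose-response fitting with AIC model
    selection; and a synthetic-data generator reproducing the measurement
    structure of gamma-counter uptake assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
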