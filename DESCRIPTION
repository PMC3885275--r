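Package: clotbg
Title: Lumped-Parameter Simulation of Blood Clot Extraction by Aspiration
    Thrombectomy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A one-dimensional lumped-parameter (bond-graph style) model of a
    blood clot lodged in a cerebral artery and extracted by an aspiration
    thrombectomy device. The clot is a chain of partitions (mass, spring,
    damper) held to the artery wall by platelet-derived adhesion forces and by
    static/dynamic wall friction, and is driven by an aspiration pressure
    program optionally modulated by a piecewise-polynomial cardiac pressure
    waveform. Detachment is event-driven: each partition releases when the
    force transmitted to it exceeds its adhesion force. The package provides
    scenario configuration with explicit units, adhesion geometry (including
    stenosed arteries), time integration with event location, extraction-time
    measurement, pressure sweeps with bisection refinement of the minimum
    effective suction, and CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
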