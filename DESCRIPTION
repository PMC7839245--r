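Package: pvvent
Title: Physiologically Variable Ventilation Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying physiologically variable ventilation (PVV)
    against monotonous pressure-controlled ventilation (PCV) on a mechanical
    lung model with derecruitment. Derives PVV driving patterns from
    spontaneous-breathing recordings (breath detection, artifact exclusion,
    ratio-preserving normalization and rescaling), simulates pressure-controlled
    breaths on a single-compartment lung with recruitment/derecruitment
    dynamics, estimates respiratory input impedance by the forced oscillation
    technique and fits the airway-tissue (constant-phase) mechanics model,
    computes oxygenation index and intrapulmonary shunt fraction from oxygen
    contents, quantifies lung aeration and airspace size (mean linear
    intercept) on 2-D images, and reproduces two-group sample-size planning.
    Seeded synthetic-data generators provide every input with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    pracma,
    signal,
    png,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
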