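Package: vsdlamina
Title: Laminar Analysis of Voltage-Sensitive Dye and Field Potential
    Recordings from Auditory Thalamocortical Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing evoked cortical activity recorded with a
    464-element hexagonal photodiode array (voltage-sensitive dye imaging)
    together with simultaneous local field potentials, in auditory
    thalamocortical brain slices.  Converts raw diode intensities to
    fractional fluorescence (dI/I), extracts layer-resolved amplitude and
    latency, scores field-potential peak-to-peak amplitude and population
    spikes, builds input/output curves and laminar spatiotemporal heat maps,
    quantifies conditioned-freezing discrimination, and provides the
    matching inferential layer (one-way, factorial and mixed ANOVA with
    Newman-Keuls, Bonferroni and Tukey post hoc procedures).  A synthetic
    cohort generator with per-condition presets produces recording bundles
    and behaviour sessions with known ground truth, so every stage of the
    pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    car
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
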