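Package: cardiolpm
Title: Lumped-Parameter Simulation of the Left Heart and Systemic Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter) model of the left
    heart and systemic circulation: a time-varying elastance left atrium and
    ventricle, diode heart valves, a resistance-compliance (Windkessel)
    arterial bed and a venous reservoir.  Ships parameter presets for normal
    physiology and graded hypertension, heart failure and haemorrhagic shock,
    integrates the system to periodic steady state, extracts standard
    haemodynamic indices (systolic/diastolic/mean arterial pressure, stroke
    volume, cardiac output, ejection fraction), generates pressure-volume
    loops, and classifies the simulated outputs against guideline-derived
    disease-severity bands.  Includes a command-line interface for batch runs
    and baseline-comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
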