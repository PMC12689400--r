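Package: aprvtitrate
Title: Computationally Directed Expiratory Duration Titration for Airway
    Pressure Release Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for setting the expiratory (release) duration T_Low in
    airway pressure release ventilation (APRV) from respiratory mechanics.
    Estimates the coefficients of a nonlinear single-compartment equation of
    motion (flow-dependent resistance, volume-dependent elastance) from
    airway pressure and flow waveforms by multiple linear regression, runs a
    T_Low titration across a grid of candidate durations, fits a
    fourth-degree smoothing spline to the resulting volume-dependent
    elastance curve, and recommends the T_Low at the maximum of the spline's
    second derivative. Includes a nonlinear lung simulator with optional
    pressure-dependent recruitment dynamics that generates waveforms with
    known ground-truth mechanics, plus a command-line interface for
    simulation, fitting, and titration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    splines,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
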