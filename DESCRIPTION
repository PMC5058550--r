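Package: csfflow
Title: Pulsatile Cerebrospinal Fluid Flow Simulation and Hydrodynamic Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of pulsatile cerebrospinal fluid
    (CSF) flow in idealized craniospinal geometries. Provides periodic cubic-spline
    handling of phase-contrast MRI style volumetric flux waveforms, a synthetic
    waveform and geometry generator calibrated to published cycle-timing
    statistics, an incompressible Navier-Stokes solver using a semi-implicit
    incremental pressure-correction (IPCS) fractional-step scheme on structured
    staggered grids (planar and axisymmetric, boundary-fitted stenosis mapping),
    flux-distributing wall-distance boundary profiles, hydrodynamic measures
    (pressure drop, resistance, phase difference, peak velocity, bidirectional
    flow fraction), analytic oscillatory-channel and Poiseuille oracles, and
    mesh-independence error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
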