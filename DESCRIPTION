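Package: graftflow
Title: Lumped-Parameter Haemodynamics of LVAD Outflow-Graft Anastomosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale haemodynamic modelling of the anastomosis of a
    HeartMate III left ventricular assist device (LVAD) outflow graft to the
    aorta. Synthesizes the pump's artificial-pulse flow waveform and the
    residual native cardiac cycle as truncated Fourier series, estimates and
    solves three-element Windkessel (RCR) outlet models, simulates a 0D
    aortic flow network with mass-conserving node algebra, enumerates
    parametric anastomosis geometries and emits idealised surface meshes,
    computes near-wall and field haemodynamic metrics (TAWSS, OSI, vorticity,
    turbulent kinetic energy, viscous energy loss, reverse flow), and performs
    Richardson-extrapolation grid-convergence (GCI) analysis. Ships seeded
    synthetic field generators with closed-form expectations so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
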