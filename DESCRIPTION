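Package: illuminoise
Title: Equivalent-Noise Analysis of Scene Lighting Direction Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for psychophysical studies of how observers estimate the
    direction of lighting in scenes containing multiple objects. Provides
    parametric stimulus specification (object layouts, per-object light
    azimuths, truncated-Beta reflectances, sinusoidally distorted
    "potato" meshes), the Psi-marginal adaptive staircase with
    expected-entropy stimulus placement, simulated observers that average
    a limited number of objects under internal noise, hierarchical
    Bayesian psychometric fitting for left/right direction judgements
    (plain and wrapped cumulative Normal, with the equivalent-noise
    spread decomposition) and for 2AFC shape identification (Weibull),
    posterior retrodictive checks, and a residual-based attribution of
    which objects drive the judgements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
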