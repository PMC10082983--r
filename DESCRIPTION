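Package: retivel
Title: Retinal Venous Pulse Wave Velocity from Modified Photoplethysmography Video
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pixelwise harmonic regression analysis of retinal fundus video for
    mapping vascular pulsation. Each pixel's green-channel intensity series,
    expressed on a cardiac-cycle-fraction time axis, is fitted with a Fourier
    harmonic model plus a truncated linear-spline drift term under AR(1) errors
    with the autocorrelation estimated by restricted maximum likelihood. The
    fitted periodic component yields harmonic regression wave amplitude (HRWa)
    and time-to-trough maps, from which pulse transit time between two vessel
    sites and the empirical retinal venous pulse wave velocity are computed
    over a spatially calibrated geodesic vessel path. A synthetic retinal
    video generator with known ground-truth propagation velocity makes the
    whole pipeline testable without acquisition hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
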