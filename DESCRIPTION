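Package: txmsim
Title: Partially Coherent Mie Image Formation for Transmission X-Ray Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models of image formation in a full-field transmission
    X-ray microscope (TXM) imaging metallic nanospheres. Implements a partially
    coherent Mie model (pc-Mie): the scattering amplitude of a homogeneous
    sphere is computed by the Mie series or its anomalous-diffraction and
    eikonal approximations, propagated together with the oblique illuminating
    plane wave through a zone-plate objective treated as a thin lens, and
    summed in intensity over azimuthal coherence patches of the annular
    condenser illumination, including a tilted-condenser variant. Also
    provides the incoherent Beer's-law comparison model (absorption density
    convolved with the objective's 3D point-spread function), quantitative
    analysis of focal stacks (best-focus finding, radial intensity profiles,
    integrated absorption versus Beer's law), and a synthetic acquisition
    module (photon noise, source flicker, stage jitter) with the matching
    registration and deflicker corrections, so the analysis chain can be
    validated end to end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
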