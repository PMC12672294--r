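Package: mxt43
Title: TG-43 Dosimetric Characterization of a Miniature X-Ray Tube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives AAPM TG-43 dosimetric parameters (dose-rate constant,
    radial dose function, anisotropy function and azimuthal dependence) for a
    kilovoltage electronic brachytherapy source from voxelized dose-rate
    grids, converts parameters measured in an ABS plastic phantom to water
    via a distance-dependent material conversion function, processes
    radiochromic-film scans through net-optical-density calibration, and
    assembles a Type A / Type B measurement uncertainty budget combined in
    quadrature. A seeded synthetic dose-kernel simulator with inverse-square
    falloff, medium-dependent beam-hardening attenuation, forward-peaked
    polar anisotropy and azimuthal ripple stands in for Monte Carlo transport
    so that every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
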