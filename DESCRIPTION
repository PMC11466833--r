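Package: stokescam
Title: Single-Molecule Orientation Imaging with a Polarization Camera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for single-molecule orientation
    localization microscopy (SMOLM) with a division-of-focal-plane
    polarization camera. Includes a vectorial dipole-spread-function
    simulator with micropolarizer mosaic and CMOS noise models, Stokes
    parameter demosaicking (Fourier demodulation and cubic-spline channel
    interpolation), a fast intensity-only single-molecule pipeline that
    estimates position, in-plane and out-of-plane orientation and a
    rotational-mobility proxy from Stokes maps, Fourier-domain optimal
    pixel-size design, drift correction, Fourier ring correlation and
    polarization-resolved rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
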