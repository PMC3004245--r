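Package: uvcentre
Title: Automated Crystal Centring from Visible and UV-Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage automated centring of loop-mounted macromolecular
    crystals on a goniometer, as used on protein crystallography beamlines.
    Stage one recognises the sample holder on visible backlight images (tip
    detection, normalized cross-correlation pattern matching of the
    neck-and-shoulders silhouette, bounding box and centre of mass, with a
    spherical fallback model for non-standard holders). Stage two segments
    the intrinsically fluorescing crystal in UV images after removal of the
    holder contour, using Laplacian-of-Gaussian zero-crossing edge detection,
    and centres its intensity centre of mass. Per-angle image offsets are
    combined into a single 3D stage translation by least squares over the
    omega rotation. A dose-budget module accounts for the accumulated UV
    exposure and compares it against a published damage threshold. A
    synthetic-scene generator renders visible and UV frames of loop-mounted
    crystals with exact ground truth so the whole pipeline is testable
    without beamline hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
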