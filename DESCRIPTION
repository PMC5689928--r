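Package: radproj
Title: Radial Projection Post-Processing of Monte Carlo Pencil-Beam Dose Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processes Monte-Carlo-generated 3D dose grids of axially
    symmetric pencil beams with the radial projection (RP) method: voxel
    scores on a lateral scoring plane are grouped by their exact radial
    distance from the beam center (integer sum-of-two-squares keys), point
    averages are taken per radius, a threshold locates the boundary between
    the high-dose and low-dose regions, and variable-width interval averages
    smooth the low-dose tail. Includes relative-standard-error analysis of
    the resulting profiles, a seeded synthetic double-Gaussian beam simulator
    with Poisson counting noise for end-to-end testing without external data,
    readers and writers for sparse ASCII dose-grid formats, and square-field
    output-factor synthesis by spot superposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
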