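Package: vfsmap
Title: Visual Field Sign Analysis of Retinotopic Cortical Maps
Version: 0.1.0
Authors@R: person("Map", "Analysis", email = "maps@example.org", role = c("aut", "cre"))
Description: Tools for analyzing dense microelectrode retinotopic mapping data
    from flattened cortex. Reads seven-parameter receptive field tables
    (cortical position, receptive field center eccentricity and polar angle,
    and ellipse size/orientation), aligns penetration coordinates to stained
    flatmounts with a landmark-based deformable warp, interpolates eccentricity
    and polar angle onto regular cortical grids with a Gaussian
    distance-weighted kernel, computes local visual field sign (the clockwise
    angle between the eccentricity and polar-angle gradients, distinguishing
    mirror from nonmirror image representations), segments the sign map into
    candidate visual areas, and renders contour maps, arrow diagrams, and
    field-sign overlays as SVG. Includes a synthetic multi-area cortex
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
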