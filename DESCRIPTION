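Package: mvatlas
Title: Mitral Valve Geometry Atlases for Transcatheter Edge-to-Edge Repair Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building synthetic mitral-valve (MV) geometry atlases
    for MitraClip outcome studies. Provides a parametric template valve mesh
    driven by six morphological scalars (anterior leaflet depth, three
    posterior scallop depths, aorto-mural and intercommissural annular
    diameters), landmark-driven radial-basis-function mesh morphing, an
    emulated multi-view echocardiographic key-point digitization and
    triangulation pipeline, literature-percentile parameter enumeration, a
    PCA point-distribution shape model with virtual-valve sampling, clip
    scenario enumeration with geometric edge-to-edge clip application and
    orifice-area metrics, and a fiber-reinforced hyperelastic constitutive
    law evaluated at material points with analytic Cauchy stress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
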