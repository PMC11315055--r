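Package: endosr
Title: Endoscopy-Style Image Super-Resolution and Multi-View 3D Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-image super-resolution for low-resolution, highly textured
    endoscopy-like images using omnidirectional (spatial + channel)
    self-attention, multi-scale window/grid attention aggregation, dual-stream
    adaptive attention fusion and dynamic edge adjustment, trained with a
    built-in reverse-mode automatic-differentiation engine.  The enhanced
    images feed a miniature incremental structure-from-motion and plane-sweep
    multi-view-stereo stage that produces sparse point clouds, per-view depth
    maps, fused oriented dense clouds and screened-Poisson surface meshes with
    summary quality metrics.  Includes a synthetic-data module that renders
    endoscopy-like textures and multi-view interior scenes with exact
    ground-truth cameras and depth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
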