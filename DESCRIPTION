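Package: LesionDepth
Title: Depth Estimation and 3D Reconstruction of Skin Lesions from Single Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Estimates and visualizes the sub-surface depth of a skin lesion
        from a single dermatoscopic-style RGB image. The pipeline localizes
        the lesion with a gradient class activation map computed from a
        pluggable convolutional model, derives a dense depth-proxy map from
        single-image defocus blur measured at Canny edges and propagated
        inward, converts the map to a 3D depth point cloud through a
        four-filter Gabor bank on a diverging red-blue scale, quantifies
        sub-surface involvement by counting red spots in 100-unit depth
        bands, and reconstructs the lesion as a conic surface with
        decreasing widths exportable as OBJ/PLY meshes for external 3D or
        mixed-reality viewers. A synthetic-fixture generator emulates
        lesion images and inverse-designs depth point clouds so the whole
        pipeline is testable without any archive download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, png, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
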