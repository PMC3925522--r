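Package: quadzone
Title: Safe and Dangerous Screw-Placement Zones on the Quadrilateral Surface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of screw placement on the quadrilateral surface
    of the pelvis through a simulated Stoppa incision. Offsets ("shells") an
    acetabular articular surface model by clinically derived clearances,
    determines which parts of the quadrilateral surface are occluded by the
    offset shells from viewpoints constrained to the incision, classifies
    absolute-dangerous, relatively-dangerous and absolute-safe entry zones,
    extracts the extremal landmark points E, F, G and H, and measures the
    landmark distances EK, FK, GM, GN, HP and HQ relative to the pelvic brim
    and obturator foramen. Includes triangle-mesh I/O (STL, PLY, OBJ),
    ray-casting and distance-field kernels, and a parametric hemipelvis
    phantom generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
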