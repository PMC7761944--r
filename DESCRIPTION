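Package: occlusalWear
Title: Occlusal Tooth Wear Volumetry from Serial Dental Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures occlusal tooth wear volume from serial (baseline and
    follow-up) triangle surface meshes of dental crowns by rigid 3D
    superimposition, in the challenging situation where non-occlusal tooth
    surfaces have also changed, for example after bonding of a lingual wire
    retainer. Implements a trimmed, point-to-plane iterative closest point
    registration with configurable estimated-overlap trimming and overhang
    exclusion, eight reference-area/overlap superimposition techniques, a
    plane-slicing and planar hole-filling workflow that yields watertight
    crown parts whose volume difference is the wear volume, a parametric
    generator of synthetic anterior-tooth arch segments with known removed
    volume for validation, and a nonparametric benchmarking harness
    (trueness/precision summaries, Bland-Altman agreement, Friedman and
    rank-based tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
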