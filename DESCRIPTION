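Package: shapenet
Title: Procedural Geometric Shape Benchmarks and Transfer-of-Learning
    Metrics for Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Procedurally generates datasets of geometric shapes whose
    classes differ either by local features (angles, parallelism of
    sides) or by global topological invariants (presence of a hole,
    connectivity, inside/outside relationship), with pixel-level
    topological verification of every generated image.  Runs
    learning-to-transfer binary classification experiments with
    pluggable classifiers and quantifies transfer of learning with the
    Transfer Index, the ratio of half-areas above chance under the
    transfer and learning accuracy curves, together with the
    learning-vs-transfer regression summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
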