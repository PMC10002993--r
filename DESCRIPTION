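Package: dbsreco
Title: Stereotactic Geometry and Method Agreement for DBS Electrode Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-level tools for comparing postoperative deep brain
    stimulation (DBS) electrode reconstructions between localization methods in
    the AC-PC stereotactic frame. Provides electrode contact interpolation
    along a two-point trajectory with configurable lead geometry, AC-PC frame
    construction and hemisphere pooling conventions, triangulated-mesh geometry
    for subcortical structures (axial cross-sections, red-nucleus ray
    construction to the ventral subthalamic border, point-in-mesh subregion
    overlap), microelectrode-recording depth validation, the paired statistical
    ladder (Lilliefors-gated paired t / Wilcoxon, repeated-measures Tukey /
    Friedman-Dunn), and a fully seeded synthetic cohort generator so the whole
    pipeline runs and is testable without patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
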