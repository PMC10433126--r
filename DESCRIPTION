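Package: bed3d
Title: Three-Dimensional Biologically Effective Dose Analysis for
    Multi-Isocenter Gamma Knife Radiosurgery Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise physical dose and biologically effective
    dose (BED) distributions for multi-isocenter Gamma Knife (Model B/C)
    radiosurgery plans directly from shot parameters (isocenter
    coordinates, collimator, dose rate, beam-on time, inter-shot gaps)
    and measured single-shot dose-falloff profiles.  Per-axis falloff
    curves are fitted with Gaussian sums, collapsed to a radial profile
    over an ellipsoid-expansion coefficient, and superposed on a 1-mm
    Leksell calculation matrix.  BED uses the linear-quadratic model with
    bi-exponential sublethal-damage repair (fast/slow partition) and a
    generalised Lea-Catcheside interaction factor over the exposure
    sequence, evaluated as grid-level quadratic forms.  Includes
    (BED-)dose-volume histograms, Paddick conformity and gradient
    indices, iso-surface extraction, plain-text NRRD/CSV/JSON round
    trips, and synthetic fixture generators for profiles, plans and
    structure masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
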