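Package: rbctweezer
Title: Optical-Tweezer Elasticity Analysis of Sickle-Trait and Sickle-Anemia Red Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing red blood cell (RBC) deformability measured
    with laser tweezers. Implements a cylindrical-dipole model of the optical
    trapping force on an RBC in a focused Gaussian beam (closed form with
    modified-Bessel correction, small-offset approximation, and an independent
    quadrature evaluation), Stokes drag calibration for stage-motion
    stretching, synthetic microscopy image rendering with segmentation-based
    morphometry, per-cell elasticity metrics (percent difference in radius and
    area, stiffness, axis ratio), sort-and-delete outlier trimming recipes,
    and two-cohort descriptive and t-test statistics. A synthetic-cohort
    generator reproduces the statistical structure of published sickle-cell
    trait (HbAS) versus sickle-cell anemia (HbSS) experiments so the full
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
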