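Package: graintex
Title: Microstructure, Texture and Milling Analysis of Cereal Grain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cereal grain endosperm microstructure from binary
    scanning-electron micrographs and relates it to kernel morphometrics and
    milling behaviour. Provides Minkowski functionals (solid-phase share,
    interphase boundary share, Euler-Poincare characteristic), watershed
    segmentation and A/B/C size-class typing of starch granules, fractal
    surface-texture metrics from the structure function (fractal dimension D,
    scaling factor K, corner scale length tau_c) and the autocorrelation
    surface-anisotropy ratio Str, kernel shape descriptors (mean diameter,
    thinness ratio, circularity), specific milling energy, laser-diffraction
    particle-size summaries (d10/d50/d90, SPAN, volume-weighted mean) and
    gelatinization endpoint bookkeeping, plus the descriptive/ANOVA-Duncan/
    Kruskal-Wallis/Pearson statistical battery used in grain-quality studies.
    Synthetic generators with analytically known ground truth (self-affine
    surfaces, anisotropic Gaussian fields, granule packings, elliptical kernel
    silhouettes, lognormal particle-size mixtures) make every stage testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    png,
    tiff,
    yaml,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
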