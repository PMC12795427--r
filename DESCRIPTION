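Package: retquant
Title: Retinal OCT/OCTA Quantification and Water-Maze Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for longitudinal retinal imaging studies in
    mouse models of neurodegeneration. Provides layer-thickness zonation around
    the optic nerve head from depolarization-flattened OCT volumes, SNR-gated
    vessel-density measurement in the three retinal vascular plexuses from OCT
    angiography, Morris water maze trajectory metrics, and the longitudinal
    mixed-model and correlation statistics linking retinal structure to spatial
    memory. Ships a synthetic-data module (layered retinal phantoms with known
    boundary surfaces and vessel density, parameterized swim-path simulation,
    and longitudinal cohort generation with configurable group effects) so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    tiff,
    lme4,
    emmeans,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
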