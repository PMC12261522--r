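Package: scintigan
Title: Conditional WGAN-GP Surrogates for Optical Photon Transport in
    Scintillation Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Replaces per-photon Monte Carlo optical transport in a cuboid
    scintillator with a learned generative surrogate. Provides a desk-scale
    photon transport simulator (isotropic scintillation emission, exponential
    bulk attenuation, Lambertian diffuse reflectors, unpolarized Fresnel
    transmission at the photodetector face), phase-space table tooling
    (emission grids, z-score normalization with persisted statistics, CSV and
    Parquet I/O), a conditional Wasserstein GAN with gradient penalty trained
    on phase-space tables conditioned on the emission point, an end-to-end
    generation pipeline (per-event photon counts and emission coordinates in,
    detector-face phase space out), and histogram Jensen-Shannon distance
    evaluation of distribution similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
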