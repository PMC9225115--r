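Package: t1rhomap
Title: Embedded Model-Based T1rho Mapping from Undersampled k-Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Direct (embedded) reconstruction of quantitative T1rho,
    S0 and phase maps from undersampled multi-contrast MRI k-space data
    via non-linear primal-dual proximal splitting, together with two
    total-variation compressed-sensing reference reconstructions solved
    by the Chambolle-Pock algorithm, a zero-filled inverse FFT reference,
    pixel-wise mono-exponential relaxation fitting, and a synthetic
    golden-angle radial / cartesian phantom acquisition simulator for
    end-to-end evaluation of the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
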