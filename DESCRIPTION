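Package: lofimri
Title: Accelerated Low-Field MRI via Retrospective Undersampling and
    Residual U-Net Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying deep-learning reconstruction of undersampled
    low-field MRI. Provides synthetic complex-valued 3D phantoms emulating
    low-field gradient-echo acquisitions, centered unitary Fourier transforms
    between image and k-space, variable-density 2D Gaussian sampling patterns
    with fully sampled center lines and exact acceleration budgets, seeded
    geometric augmentation applied jointly to real and imaginary channels, a
    2-channel residual U-net trained with RMSProp on a mean-squared-error loss,
    and an ROI-masked evaluation protocol (PSNR, SSIM, NRMSE, gradient
    sharpness) with noise-only slice exclusion. A pipeline layer orchestrates
    simulation, mask design, dataset preparation, training, reconstruction and
    evaluation from a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
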