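Package: cestlab
Title: Synthetic CEST MRI Phantoms and a Denoising Laboratory
Version: 0.1.0
Authors@R:
    person("MR Methods", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end laboratory for chemical exchange saturation
    transfer (CEST) MRI denoising research. Generates randomized layered
    2D digital phantoms, simulates voxel-wise Z-spectra by numerically
    solving the multi-pool Bloch-McConnell equations under pulsed Gaussian
    saturation, corrupts images with a Fourier-domain (k-space) Gaussian
    noise model, and benchmarks analytical denoisers (spectral PCA with
    median, Nelson and Malinowski component-selection criteria, non-local
    means, BM3D) against trainable U-Net and residual U-Net convolutional
    autoencoders in noise-estimation and direct modes. Includes PSNR
    evaluation sweeps, WASSR-style B0 self-correction, and MTR asymmetry
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
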