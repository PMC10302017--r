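Package: dwisr
Title: Super-Resolution Reconstruction of Diffusion-Weighted MRI from Sparse k-q Space Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accelerated diffusion-weighted MRI (DWI) reconstruction from
    highly sparse, jointly sampled k-q space data. Generates PROPELLER blade,
    Poisson-disc and partial-Fourier sampling patterns with one rotating blade per
    diffusion direction; reconstructs low-resolution DW images by NUFFT, zero
    filling, Hermitian (conjugate-symmetry) completion, POCS partial-Fourier and
    data-consistency cascades, and a neighbor-direction composite that exploits
    the smoothness of diffusion contrast across adjacent q-space directions;
    estimates in-plane motion by exact discrete displacement labeling on a
    minimum spanning tree; and provides adversarially trained (Wasserstein GAN)
    super-resolution, deblurring and Rician denoising stages with a
    self-contained neural-network core. Includes analytic phantoms, degradation
    models, PSNR/SSIM/TRE evaluation and an end-to-end pipeline, all
    deterministic under a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    RNifti,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
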