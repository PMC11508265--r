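Package: adcgan
Title: Unpaired Synthesis of Apparent Diffusion Coefficient Maps from
    T2-Weighted Prostate MRI
Version: 0.1.0
Authors@R:
    person("Bengi", "Okur", email = "bengi.okur@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic apparent-diffusion-coefficient (ADC) maps
    from T2-weighted prostate MRI using unpaired image-to-image translation.
    The model couples a ResNet generator carrying a convolutional block
    attention module (CBAM) with a PatchGAN discriminator, and is trained
    with a least-squares adversarial loss, patch-wise contrastive (NCE)
    losses computed through SimCLR-style projection heads, and a pixel-level
    self-regularization term. Includes the full preprocessing chain for
    NIfTI volumes (resampling, z-score normalization, prostate-mask-guided
    cropping, slice extraction), evaluation metrics (PSNR, SSIM with its
    luminance/contrast/structure decomposition, Frechet distance between
    Gaussian feature moments, Dice), and a synthetic prostate-phantom
    generator so that every stage is testable without clinical data. All
    neural-network layers and their gradients are implemented natively
    (RcppArmadillo convolutions), so training and inference run on a single
    CPU with no deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
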