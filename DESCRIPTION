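Package: mrsr
Title: Multimodal Superresolution Reconstruction of 3D MR Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a high-resolution version of a low-resolution 3D
    magnetic-resonance volume by borrowing voxel-similarity structure from a
    coplanar high-resolution reference volume of another contrast, while
    enforcing exact consistency with the boxcar-averaging acquisition model.
    Provides the acquisition (degradation) model with Rician noise
    simulation, a Rician-bias-corrected nonlocal-means denoiser, the
    iterative reference-guided reconstruction with decremental filtering
    strength and mean-absolute-difference stopping, interpolation baselines
    with PSNR/IPSNR evaluation, a paired-contrast synthetic brain phantom
    generator, NIfTI-1 input/output, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
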