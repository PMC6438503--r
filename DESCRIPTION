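Package: dividemri
Title: Diffusional Variance Decomposition for Tensor-Valued Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diffusional variance decomposition (DIVIDE) analysis of
    diffusion MRI acquired with tensor-valued encoding. Provides b-tensor
    algebra and numerical integration of b-tensors from effective gradient
    waveforms, construction of linear plus spherical tensor-encoding sampling
    protocols, a multi-Gaussian two-compartment signal simulator with Rician
    noise, joint gamma-model fitting of powder-averaged signals into mean
    diffusivity, isotropic and anisotropic diffusional variance, kurtosis-style
    metrics and microscopic fractional anisotropy, computation of the minimal
    direction count for rotation-invariant powder averaging, and SNR and
    test-retest repeatability quality statistics.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
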