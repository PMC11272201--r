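Package: dtialps
Title: Diffusion Tensor Image Analysis Along the Perivascular Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested toolkit for the DTI-ALPS (diffusion tensor image
    analysis along the perivascular space) glymphatic index. Reads
    single-shell diffusion MRI in NIfTI format with FSL-dialect gradient
    tables, fits the diffusion tensor per voxel (ordinary or weighted least
    squares), derives fractional anisotropy and axis-diffusivity maps,
    places the published spherical regions of interest on template grids,
    and computes left, right and mean ALPS indices. A phantom simulator
    generates single-shell acquisitions with known analytic ALPS indices
    and multi-scanner cohort structure for validation. A reliability module
    implements two-way random-effects intraclass correlation coefficients
    (consistency and absolute-agreement forms, single measures) with
    McGraw-Wong confidence intervals, pairwise ICCs, Bland-Altman limits of
    agreement and the conventional interpretation bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
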