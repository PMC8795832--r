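Package: sact
Title: Sparse-View Computed Tomography Reconstruction by Simulated Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ultralow-dose (sparse-view) parallel-beam computed
    tomography reconstruction by simulated annealing. Provides a discrete
    Radon forward projector, a wavelet-multiscale filtered back-projection
    initialization template, a bank of seven projection-domain cost
    functions (UIQI, RSE, SSIM, MAE, RAE, RMSE, RMSLE), a Metropolis
    annealing engine with a hyperbolic-cosine cooling profile, filtered
    back-projection and algebraic reconstruction (Kaczmarz) baselines,
    image quality metrics (PSNR, relative Euclidean error, weighted PSNR),
    Student-t repetition statistics, and a seeded procedural lung phantom
    generator for benchmarking cost-function sensitivity.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
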