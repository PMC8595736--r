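Package: gleml
Title: Generalized Langevin Equation Models of Lateral Membrane Diffusion
    with Mittag-Leffler Memory Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the lateral diffusion of a membrane protein with a
    generalized Langevin equation whose memory kernel combines an
    instantaneous viscous term and a three-parameter Mittag-Leffler
    (Prabhakar) elastic term. Provides numerically robust evaluation of the
    Prabhakar function and its relaxation-rate spectrum, Laplace-domain
    relaxation functions with a numerical inverse Laplace transform engine
    (fixed Talbot and de Hoog methods), time-domain observables (mean-square
    displacement, velocity autocorrelation, time-dependent diffusion
    coefficient) with their short- and long-time asymptotic laws, estimators
    and Gaussianity diagnostics for 2D single-particle trajectories,
    Bayesian fitting of the model to MSD curves on a grid or by
    affine-invariant ensemble MCMC, and a kernel-consistent GLE simulator
    based on a Markovian embedding of the relaxation-rate spectrum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
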