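Package: affectfp
Title: Maximum-Likelihood Estimation of Bounded Gradient-Drift Diffusion
    Models of Affect Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits continuous-time bounded drift-diffusion models of
    bivariate affect (the Affective Ising Model and a bounded
    Ornstein-Uhlenbeck variant) to irregularly sampled experience-sampling
    time series by maximum likelihood. Conditional transition densities are
    obtained by propagating the model's Fokker-Planck equation on a lattice
    with a Metropolis-Hastings updating scheme and ghost-cell no-flux
    boundaries; the negative log-likelihood is minimised with a
    differential-evolution global optimizer. Includes an Euler-Maruyama
    trajectory simulator as an independent Monte-Carlo oracle, a synthetic
    experience-sampling data generator for parameter-recovery experiments,
    and solver cross-validation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
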