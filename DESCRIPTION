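Package: chronodate
Title: Bayesian Molecular-Clock Dating with Fossil Calibrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian divergence-time estimation on fixed rooted topologies.
    Implements fossil-calibration densities (soft-bounded uniform, truncated
    Cauchy, skew-t, skew-normal mixtures, gamma), a birth-death kernel prior
    on node ages, three molecular-clock models (strict, independent
    log-normal, autocorrelated geometric Brownian), exact HKY+Gamma and
    quadratic approximate likelihoods, Metropolis-Hastings MCMC, marginal
    likelihoods by thermodynamic integration with Gauss-Legendre quadrature
    for clock-model selection, sequential two-step dating via maximum
    likelihood skew-t refitting of marginal posteriors, and infinite-sites
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: ape, pracma, Rcpp, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
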