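Package: mstcar
Title: Bayesian Multivariate Space-Time CAR Models for Small-Area Death Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of county-level death rates with a Bayesian
    multivariate space-time conditional autoregressive (MSTCAR) model. Death
    counts are modelled as Poisson with log-normal rates whose random effects
    are shrunk toward neighbouring counties (intrinsic CAR), adjacent years
    (AR(1)), and correlated demographic groups (unstructured covariance with
    an inverse-Wishart prior), fitted by Metropolis-within-Gibbs MCMC.
    Includes a generative simulator for synthetic mortality data over a county
    graph, direct age-standardization to the 2000 US standard population,
    reliability-based suppression of unstable estimates, and log-linear
    annual-percent-change trend estimation carried out on posterior samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
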