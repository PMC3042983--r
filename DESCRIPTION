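Package: csfsde
Title: Stochastic Modeling of Cerebrospinal Fluid Dynamics and Intracranial Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the stochastic extension of the classic pressure-volume
    (Marmarou-type) model of cerebrospinal fluid dynamics. Intracranial
    pressure is modeled as a stochastic logistic Ito diffusion with
    multiplicative noise; the package provides the closed-form path solution,
    positivity-preserving and Euler-Maruyama simulation schemes, the
    stationary gamma distribution of intracranial pressure with its existence
    condition and mean-sensitivity results, scale-function machinery for
    first-passage (clinical risk) probabilities with Monte-Carlo
    cross-validation, risk curves and surfaces over noise intensity and
    outflow resistance, a synthetic infusion-study recording generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    optparse,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    tidyr
Config/testthat/edition: 3
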