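Package: telemech
Type: Package
Title: Mechanistic and Telegraph Models of Stochastic Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic models of transcription in mammalian cells: a
    mechanistic three-state gene model with activator binding, Pol II
    pausing/release coupled to gene state, deterministic elongation delay
    and first-order mature-mRNA turnover, together with the telegraph,
    delay-telegraph and refractory models. Provides an exact delay
    stochastic simulation algorithm, exact waiting-time distributions
    between consecutive transcript production events (rational Laplace
    transforms, moments, randomness parameters, densities), steady-state
    molecule-number statistics (closed-form means and Fano factors, a
    window-count master-equation engine for active Pol II, truncated
    chemical-master-equation solves for mature mRNA, Hellinger distances),
    model-reduction machinery (feasibility criterion, closed-form
    parameter maps, fast-switching limits, number-moment matching,
    maximum-likelihood fitting, refractory four-moment matching) and
    relative-sensitivity analysis with constrained random screening.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
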