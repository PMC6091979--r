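Package: intertrial
Title: Belief-Updating and Evidence-Accumulation Models of Inter-Trial
    Effects in Pop-Out Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits trial-history models of reaction times in
    visual singleton ('pop-out') search. Combines two evidence-accumulation
    models (the LATER model and a closed-form drift-diffusion model) with
    trial-by-trial updating rules for the starting point (sequential Bayesian
    learning of prior odds with forgetting, after the Dynamic Belief Model)
    and for the accumulation rate (binary, decaying, and weight-sharing
    repetition/switch rules), crossed in a factorial model space that is
    fitted per participant by nested maximum likelihood and compared by AIC.
    Includes generators for the three experimental designs (blocked detection,
    dimension discrimination, and De Bruijn-balanced mixed detection), a
    synthetic-data simulator with lapses, parameter- and model-recovery
    harnesses, and descriptive inter-trial summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
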