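Package: dyecomp
Title: Paired Analysis and Power Simulation for Dye-Based Sperm Competition Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for reciprocal dyed/undyed sperm competition
    experiments in broadcast spawners. Provides paired comparison of
    computer-assisted sperm analysis (CASA) motility traits via principal
    components of per-male trait differences, a binomial logit generalized
    linear mixed model (random pair intercept, Laplace-approximated marginal
    likelihood, Wald t inference, deviance and Pearson dispersion diagnostics,
    observation-level random-effect variant) for competitive fertilisation
    share, simulation-based power analysis over a grid of dye effect sizes,
    and a seeded synthetic-data generator reproducing the statistical
    structure of both experiment types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
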