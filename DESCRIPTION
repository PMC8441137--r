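Package: reproaudit
Title: Staged Bayesian Models for Reproducibility Audits and Data Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the reproducibility of a research literature
    as a staged, conditional process: recovery of the underlying data,
    usability of recovered data, clarity of the published analysis, and
    agreement of re-computed results with published results. Data recovery is
    modelled as a Bernoulli outcome whose probability decays exponentially
    with publication age, separately by study type, yielding per-type data
    half-lives. The later stages are conditional binomial models with
    paper-level random intercepts and a Gaussian-process smoother over
    publication year. Includes a synthetic audit generator matching the
    design of published audits, MCMC fitting via JAGS, rank-normalised
    split R-hat and effective-sample-size diagnostics, highest-density
    intervals, prior-predictive simulation, and reporting of combined
    reproducibility rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
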