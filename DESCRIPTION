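Package: stmbound
Title: Information-Theoretic Bounds on Short-Term Memory Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the decay of short-term memory for analog variables as
    information storage in diffusive persistent-activity networks.  Implements
    two competing accounts of delayed-estimation performance: direct storage,
    in which recall error grows linearly with delay at a rate set by a pooled
    diffusivity, and coded storage, an information-theoretic lower bound on
    recall error obtained from joint source-channel coding over Gaussian
    channels.  Provides a Monte-Carlo simulator of wrapped diffusion, a
    synthetic delayed-estimation dataset generator emulating a standard
    multi-item psychophysics design, the per-(set size, delay) performance
    summary pipeline, anchored weighted-least-squares model fitting with
    parameter-landscape exploration and jackknife refits, and
    Bayesian-Information-Criterion model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
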