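Package: prc1dyn
Title: Stochastic Cell-Cycle Dynamics of PRC1 with Asymmetric Division
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for a two-phase stochastic model
    of PRC1 protein dynamics over the cell cycle: exponential degradation
    followed by exponential accumulation, with per-cell kinetic parameters
    coupled through a regression structure with Gaussian noise, and unequal
    partitioning of protein between daughter cells drawn from a symmetric Beta
    distribution. Provides a multi-generation branching-pedigree simulator, a
    synthetic single-cell trajectory generator with measurement noise and
    outlier contamination, trajectory feature extraction, Tukey-fence outlier
    filtering on the division/birth ratio, regression and division-asymmetry
    estimation, correlation-table and time-point correlation reporting, and the
    noise-free reduction to a one-dimensional size-regulation map with its
    equilibria and asymmetric-division iteration.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
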