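Package: colonyidle
Title: Colony Efficiency Under Worker Inactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates social-insect colonies in which individual worker
    performance is random and uncontrollable, and asks what fraction of
    workers a colony should keep active to maximize its efficiency. Worker
    performances are drawn from five stochastic distributions on [0, 1]
    (truncated normal, truncated bimodal mixture, uniform, and left- and
    right-skewed power transforms of the uniform); colony costs combine a
    per-worker production cost with maintenance costs scaled by the
    maintenance/production ratio (delta) and the inactive/active maintenance
    ratio (beta); only the top-performing workers are activated. Provides
    replicated Monte-Carlo parameter sweeps over (beta, delta) grids,
    normalized efficiency curves, optimal-active-fraction heat maps, CSV
    export with run manifests, and a command-line driver.
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
    parallel,
    purrr,
    readr,
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
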