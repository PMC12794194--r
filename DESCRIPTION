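Package: micellekin
Title: Micellization Kinetics and Critical Micelle Concentrations from
    Short Time Scale Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting surfactant critical micelle concentrations
    (CMCs) from short, replicated simulation runs. Implements a classical
    nucleation free-energy landscape for aggregate size distributions,
    Becker-Doring/Aniansson-Wall stepwise association kinetics with stiff
    integration and relaxation-spectrum eigenanalysis, exponential plateau
    fitting of the free-surfactant fraction with jackknife resampling and
    fit-window diagnostics, charge-phase CMC inversion for ionic surfactants,
    Stauff-Klevens homologous-series extrapolation, periodic single-linkage
    clustering of coordinate frames into aggregates, and a finite-box
    synthetic-data generator emulating multi-repeat coarse-grained runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
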