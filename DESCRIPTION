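Package: saltsim
Title: Microsimulation of Salt Reduction Policies for Cardiovascular
    Disease and Gastric Cancer
Version: 0.1.0
Authors@R:
    person("saltsim", "developers", email = "saltsim@example.org",
           role = c("aut", "cre"))
Description: A discrete-time, dynamic, stochastic microsimulation of an
    English-like synthetic adult population under counterfactual dietary
    salt policy scenarios. Survey-like waves of 24-hour-urine-equivalent
    salt intake are generated, a declining secular trend is fitted by
    quantile regression on a logarithmic time scale and projected forward,
    policy scenarios (freeze, continued trend, feasible and ideal targets
    drawn from PERT distributions) transform individual trajectories, and a
    lagged, multiplicative, competing-risk engine converts exposure into
    first coronary heart disease, stroke and gastric cancer events and
    deaths. Outputs include cases and deaths prevented or postponed by
    deprivation quintile, absolute and relative equity slope indices with
    direct age-sex standardisation, and second-order Monte Carlo
    uncertainty summaries (medians, IQRs and probabilities of superiority).
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
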