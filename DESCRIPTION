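Package: ltcisim
Title: Mortality Estimation, Population Projection and Long-Term Care
    Insurance Fund Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A demographic-actuarial simulation chain for data-sparse
    settings: abridged and single-age life-table construction; estimation
    of annual mortality from census-year targets with the three-parameter
    log-quadratic (DCMD-style) model life-table system, including an
    old-age intercept adjustment and monotone cubic (PCHIP) interpolation
    of adult and old-age mortality between censuses; Lee-Carter mortality
    forecasting extended with rotation of the age loadings, with
    simulation-based predictive intervals for life expectancy;
    cohort-component population projection with a fertility path and net
    migration tapering to equilibrium; disability prevalence estimation
    from activities-of-daily-living survey records with severity
    classification and annual-change scenarios; and a dynamic-financing
    actuarial model of a fixed-amount-premium long-term care insurance
    fund, including the search for the minimal sustainable premium growth
    rate. A synthetic-data generator emulates the census, child-mortality
    and disability-survey inputs so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
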