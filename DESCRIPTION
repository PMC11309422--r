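Package: hscsim
Title: Stochastic Rule-Based Simulation of Hepatic Stellate Cell Dynamics
    in Liver Fibrosis and Reversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic (Gillespie direct-method) simulation of hepatic
    stellate cell (HSC) populations during liver fibrosis and its reversion.
    Cells are agents with a categorical state (quiescent, activated,
    myofibroblast, inactivated, reactivated and apoptotic/senescent states),
    a TGFbeta1 binding site, a receptor trafficking site and a bounded
    differentiation counter; TGFbeta1 and type I collagen are continuous
    token pools coupled to the agents through hybrid rules. The package
    provides three nested model families differing in the fate of
    reactivated myofibroblasts and inactivated cells, the published
    stimulation protocols (chronic twice-weekly injury, CCl4-like schedules,
    relapse cycles, dose/periodicity scans), replicate aggregation of the
    standard observables (alpha-SMA positive cells, total collagen,
    iHSC/qHSC balance), and a block-based calibration routine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    readxl,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
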