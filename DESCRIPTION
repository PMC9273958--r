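Package: debibm
Title: Coupled Dynamic Energy Budget and Individual-Based Population Model for Hairtail
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a coupled dynamic energy budget (DEB) and
    individual-based population model (DEB-IBM) for the hairtail
    Trichiurus lepturus in the East China Sea. The individual level is an
    abj-type DEB model with metabolic acceleration, a five-parameter
    Arrhenius temperature correction and an embryo initial-reserve solver.
    An Add-my-Pet style trait layer predicts zero-variate life-history
    traits, evaluates the multiplicative symmetric bounded loss and
    MRE/SMSE goodness-of-fit criteria, and calibrates parameters by
    Nelder-Mead. The population level tracks super-individual cohorts
    through degree-day hatching, density-dependent, environment-dependent,
    egg-predation, ageing and fishing mortalities on an hourly scheduler
    over a reference area, with a seeded synthetic environmental-forcing
    generator and climate/fishing scenario machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
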