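Package: OleFe
Title: Stoichiometric and Thermodynamic Accounting for Anaerobic Oleate
    Degradation under Iron-Reducing and Methanogenic Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact reaction algebra and electron-equivalent bookkeeping for
    anaerobic long-chain fatty acid (LCFA) degradation experiments in which
    ferric hydroxide competes with methanogenesis for reducing equivalents.
    Provides rational-arithmetic composition of half-reactions with elemental
    and charge balance verification, standard transformed Gibbs energy (dG0')
    combination with Hess-law consistency checks, theoretical yield and
    methane-recovery computation, partitioning of electron equivalents
    between Fe(III) reduction and methanogenesis, incubation time-series
    descriptors (lag time, windowed production rate, maximum cumulative
    product), and a synthetic incubation-data generator built on a
    modified-Gompertz curve model so that every stage is testable without
    measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'OleFe-package.R'
    'rational.R'
    'species.R'
    'reaction.R'
    'compose.R'
    'ledger.R'
    'reports.R'
    'synthetic.R'
    'timeseries.R'
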