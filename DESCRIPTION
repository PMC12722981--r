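Package: hccpsm
Title: Partitioned-Survival Cost-Effectiveness Model for First-Line
    Therapy in Advanced Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state (progression-free, progressed, dead)
    partitioned survival model comparing toripalimab plus bevacizumab
    against sorafenib as first-line treatment for advanced hepatocellular
    carcinoma, from the Chinese healthcare system perspective. Provides
    pseudo individual-patient-data reconstruction from digitized
    Kaplan-Meier coordinates and number-at-risk tables (Guyot algorithm),
    parametric survival fitting over seven candidate families with
    AIC/BIC selection, discounted life-year/QALY and cost accrual with
    dose-based drug costing, scenario analysis, one-way deterministic
    sensitivity analysis with tornado ordering, and Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. A synthetic-data module generates survival
    datasets and digitized-curve artifacts with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
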