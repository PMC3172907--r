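Package: amprisk
Title: Lifetime Cancer Risk Estimation Adjusted for Multiple Primaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimators of the lifetime risk of developing cancer from
    age-banded registry counts: cumulative rate, cumulative risk, the
    'current probability' life-table method, the adjusted-for-multiple-
    primaries (AMP) estimator, and the first-primaries 'gold standard'.
    Includes the ground-truth mathematics of the underlying four-state
    illness-death model with piecewise-constant hazards (state occupancies,
    true first-cancer risk, expected primaries per lifetime, observable
    population rates) and a continuous-time cohort microsimulation that
    aggregates individual event histories into registry-style tables for
    validating each estimator against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
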