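Package: ckdcea
Title: Markov Cohort Cost-Effectiveness Model for Cardiorenal Therapy in
    Chronic Kidney Disease with Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-level Markov decision model for evaluating the
    cost-effectiveness of adding finerenone, a sodium-glucose cotransporter-2
    inhibitor (SGLT2i), or both to standard of care in patients with chronic
    kidney disease and type 2 diabetes, from a Chinese healthcare-system
    perspective. Health states follow CKD stage, renal replacement therapy
    (acute and post-acute dialysis and transplantation) and cardiovascular
    event history; treatment effects enter as hazard-ratio and eGFR-slope
    adjustments of the standard-of-care transition probabilities. The package
    provides deterministic base-case and scenario analyses, one-way
    sensitivity analysis with tornado ranking, and probabilistic sensitivity
    analysis with cost-effectiveness plane and acceptability-curve outputs,
    plus a generator of random structurally valid parameter sets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
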