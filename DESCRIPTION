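Package: pathcost
Title: Micro-Costing of a UK Cancer Genetics Service for BRCA Testing
Version: 1.0.0
Authors@R:
    person("Pathcost", "Maintainers", email = "maintainers@pathcost.example.org",
           role = c("aut", "cre"))
Description: Bottom-up (micro-) costing model of a UK NHS cancer genetics
    service for familial breast and ovarian cancer, from referral to
    surveillance management.  Encodes the 28 referral-to-management patient
    pathways of a specialist BRCA testing service as data, costs them from a
    unit-cost table, discounts age-indexed surveillance and hormone
    replacement therapy streams at a fixed annual rate, computes expected
    carrier-management costs under probabilistic surgery uptake and 5-year
    survival, weights pathway costs by clinic audit counts, and runs one-way
    deterministic sensitivity analyses over test price, staffing mix,
    consultation mode and London weighting.  Includes a least-squares
    calibration module that recovers unpublished component prices from
    published pathway totals, and a seeded synthetic-cohort generator for
    end-to-end testing with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
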