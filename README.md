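# pathcost

Bottom-up (micro-)costing of a UK NHS cancer genetics service for familial
breast and ovarian cancer, from referral to surveillance management.

Specialist cancer genetics clinics assess women against the NICE ≥10% BRCA
mutation-probability threshold, test those eligible (a full mutation screen,
or a predictive test where a familial mutation is already known), and assign
surveillance or risk-reducing management by the result and family history.
`pathcost` encodes the 28 distinct referral-to-management pathways of such a
service (10 for women affected by cancer, 18 for unaffected women with a
family history) as data, and provides everything needed to cost the service:

* **Cost engine** — itemized pathway costing from a unit-cost table (2013
  GBP); staff-time costs with the 1.19 London weighting and the 1:12.5
  consultant-supervision loading on genetic counsellor time; age-indexed
  surveillance schedules discounted at 3.5%/year from presentation at age
  30, with risk-reducing surgery costed undiscounted in the presentation
  year; expected carrier-management costs under 30%/60% surgery uptake and
  5-year survival of 0.70 (breast) / 0.69 (ovarian). The present value of a
  stream of dated costs is

  `PV = Σ_e c_e (1 + r)^-(a_e - a_0)`,

  with `r = 0.035`, `a_0 = 30`, and the surgery terms entering undiscounted.
* **Pathway catalog** — the 28 pathways with activity lists and a total
  `classify()` function mapping any consistent structured case description
  onto exactly one pathway.
* **Audit weighting** — six-month audit counts (220 women: 84 affected, 136
  unaffected), the 50% allocation rule for pending predictive tests, and
  subgroup/weighted means and service totals.
* **Sensitivity** — one-way scenarios over test price, consultant/counsellor
  mix, clinic/telephone mix, and London weighting.
* **Calibration** — least-squares recovery of component prices the published
  totals imply but do not print (GP referral, predictive test, per-tier
  surveillance aggregates, carrier-management bundles), with rank and
  residual reporting.
* **Synthetic cohorts** — seeded multinomial referral cohorts with known
  ground truth for end-to-end testing.

## Worked example

```r
library(pathcost)

catalog <- rms_catalog()
costs   <- read_unit_costs()
counts  <- rms_audit()                     # 220 women, pending tests allocated

pathway_cost(catalog[6, ], costs)          # the worked affected pathway
#> Pathway 6 — 18 items
#>  ...
#> Total: £1630.97                          # printed total £1630.96 (rounding)

printed <- pathway_costs(catalog, costs)
fmt_gbp(subgroup_mean(printed, 1:28))      # "£2227.39" mean pathway cost
fmt_gbp(weighted_mean_cost(printed, counts, 11:28))
#> "£1561.45"                               audit-weighted unaffected mean
fmt_gbp(service_total(printed, counts))    # "£387409.43" six-month service

apply_scenario(scenario(test_price = 300), catalog, costs, counts)
#> 375169.4                                 test at £300 (base 387409.4)

cmd_calibrate()
#> Calibration result (full rank)
#>   gp_referral                      £43.00
#>   brca_predictive_test             £107.99
#>   ...
#> max |residual|: £0.01
```

The service total is affine in the full-test price with slope 51 — the 35
full screens in affected patients plus 16 in relatives in the weighted
cohort — so the £300 scenario sits exactly `(300-540)×51 = -£12,240` below
the base case.

## Command line

```sh
inst/cli/pathcost compute --out report.json
inst/cli/pathcost sensitivity --out sens.json
inst/cli/pathcost calibrate --out calib.json
inst/cli/pathcost simulate --n 220 --seed 17 --out cohort
```

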