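---
title: "A micro-costing model of a cancer genetics service"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A micro-costing model of a cancer genetics service}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcost)
```

## The model

`pathcost` implements a healthcare-provider-perspective micro-costing of a
UK cancer genetics service for familial breast and ovarian cancer. The unit
of analysis is the *patient pathway*: one of 28 distinct routes a woman can
take from referral (through oncology if affected by cancer, through her GP
if not) to long-term management. Each pathway is an ordered list of costed
activities — referral, appointment administration, clinic consultation,
phlebotomy, BRCA testing, follow-up, and a management assignment — and the
pathway cost is the full-precision sum of its items. All costs are 2013 GBP.

Management is one of four surveillance tiers (population: 3-yearly
mammography 50–70; moderate: annual mammography 40–50 then population;
higher: annual mammography 40–50, 18-monthly 50–60, then population;
carrier: annual mammography 40–70 plus annual MRI 30–50), plus, for mutation
carriers, an expectation over risk-reducing surgery.

### Discounting

Every woman is assumed to present at age 30; that fixes the time origin.
Surveillance and hormone-replacement costs incurred at age $a$ are
discounted by $(1.035)^{-(a-30)}$; fractional elapsed years (the 18-monthly
scans) use the fractional exponent. Risk-reducing surgery is assumed to
take place in the year of diagnosis and is therefore *not* discounted.
`discount_factor()` refuses events before the reference age rather than
extrapolating.

### Staff time

Hourly rates are London-weighted (×1.19) 2013 salary mid-points; the
weighting is applied exactly once (`staff_rate()` records whether a rate
already includes it). Genetic counsellor time carries consultant
supervision at 1 hour per 12.5 hours of counsellor time, so a 45-minute
counsellor appointment costs $(55.54 + 139.73/12.5)\times 0.75 = £50.04$
against the consultant's £104.80. The 45-minute duration is inferred: it is
the unique duration at which the consultant rate reproduces the printed
clinic-appointment price.

### Carrier management

Unaffected carriers take up bilateral mastectomy with probability 0.30 and
bilateral salpingo-oophorectomy with probability 0.60, both in the
presentation year (undiscounted). For affected carriers, management at or
after 5 years from presentation is scaled by the 5-year survival
probability (0.70 breast, 0.69 ovarian), and 5% of surviving ovarian
carriers undergo mastectomy at year 5, giving the expectation
$0.69 \times 0.05 \times £6784$, undiscounted per the surgery rule. The
published analysis states these inputs but not the combination mechanics;
`carrier_interventions()` implements the choice above and every element of
it is an argument.

## Calibrated components

The published analysis prints each pathway total but not every component
price. Because each total is linear in its components, the unprinted ones
are recoverable by least squares against the 28 totals
(`solve_components()`): GP referral £43.00, predictive test £107.99,
population/moderate surveillance aggregates £169.22/£578.79, carrier
management bundles £4603.49 (affected) and £7498.90 (unaffected), and three
relative-loop blocks (£5608.54 full-test-positive, £1243.40
full-test-negative, £742.25 intervening-relative). These reproduce all 28
printed totals to the penny except pathways 6 and 7, which the printed
table itself leaves £0.01 inconsistent (its own itemization sums to
£1630.97 against a printed £1630.96); comparisons therefore use a ±£0.02
per-item-rounding band. The shipped unit-cost table carries these rows with
`source = "calibrated"`, and the calibration module re-derives them from
the totals as a standing test.

Two things are *not* recoverable and are deliberately left so. The
per-tier surveillance aggregates cannot be reproduced from first principles
under any event-grid convention at 3.5% (e.g. the higher-risk aggregate
prints £628.30 where the schedule engine yields ≈£470), so the schedule
engine is used for synthetic and exploratory work while canonical pathway
costing uses the calibrated aggregates. The hormone-replacement bundle is
never priced and never appears separately from the carrier-management
bundles in any total, so it is carried inside them and flagged
unidentifiable on its own.

## Audit weighting

The six-month audit vector (220 women) is reconstructed from the service
narrative. Two gaps required decisions:

* Four unaffected women had predictive tests pending at the window's close;
  they are allocated 50/50 between the carrier and non-carrier pathways
  (`allocate_pending()`), and the fractional counts are kept exact.
* The 10 affected women with a known familial mutation are split between
  the test-positive and test-negative pathways by brute force against the
  published affected weighted mean (`infer_affected_split()`); the unique
  minimiser is 9/1 and the shipped fixture marks those rows as inferred.

With that vector every published weighted average reproduces to the penny
except the carrier-presenting one (computed £6657.07 vs printed £6657.08,
presumably sub-penny differences in the authors' unrounded totals).

## Sensitivity analysis

One-way scenarios recompute the weighted service total. Test-price changes
move each of the 51 full tests in the weighted cohort, making the total
affine in price with slope 51 — the published test-price rows reproduce
within £1. The staffing-mix, consultation-mode and London-weighting rows
are *not* numerically reproducible: they depend on a per-appointment
substitution cost and an appointment-count basis the publication does not
state. The engine implements the mechanics with documented defaults — the
counsellor appointment derived from the salary table at the same 45-minute
duration (£50.04), the telephone appointment assumed to be 20 minutes of
consultant time (£46.58), appointment counts taken from the catalog's
activity lists (one per clinic visit, two inside each relative loop), and
the staff-time content of each composite block set to one
administration+clinic+follow-up chain (£291.67) — and the tests assert
direction and monotonicity only, not the published figures.

## Synthetic data

`sample_cohort()` draws patient pathways from a multinomial over the 28
pathways (default probabilities: the audit's empirical frequencies, n=220)
using base R's Mersenne-Twister generator under a recorded seed, and
renders each patient as a structured case record that `classify()` maps
back to its source pathway. It emulates referral-mix variation only: no
disease natural history, no test error, no within-pathway cost variation.
A green end-to-end test therefore establishes that counting, weighting and
reporting are correct under a known mixture — not that the printed unit
costs are right, which only the calibration residuals speak to.
`perturb_cost_table()` builds calibration test instances with hidden
components and optional bounded per-item rounding noise (±£0.005 mirrors
penny rounding).

## Numerical choices and limitations

* Money is double precision throughout; rounding to pennies happens only at
  display/serialization, and JSON reports serialize currency as decimal
  strings so round-trips are exact.
* Schedule grids are start-inclusive, end-exclusive; the higher tier
  re-enters the population programme at 60 on a fresh 3-year grid. These
  conventions affect only the first-principles schedule engine, not the
  calibrated canonical totals.
* Rank detection in the calibration solver uses a relative singular-value
  tolerance of 1e-8; unidentifiable components are reported as `NA`, never
  imputed, and negative estimates raise a model-structure warning.
* `infer_affected_split()` errors on ties rather than choosing silently;
  its default tolerance is half a printed penny.
* The model covers female patients on the standard BRCA pathways only
  (founder-mutation and male pathways were excluded from the audit), takes
  eligibility as an input flag rather than computing mutation probability,
  and does no outcome or cost-effectiveness modelling.
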