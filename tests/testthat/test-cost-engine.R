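test_that("discount factors match direct evaluation and boundary identities", {
  spec <- discount_spec()
  expect_identical(discount_factor(30, spec), 1)
  expect_identical(discount_factor(40, discount_spec(annual_rate = 0)), 1)
  # oracle: direct evaluation of 1.035^-10
  expect_equal(discount_factor(40, spec), 1.035^-10, tolerance = 1e-12)
  expect_equal(discount_factor(40, spec), 0.70892, tolerance = 1e-5)
  # fractional elapsed time (18-monthly grid)
  expect_equal(discount_factor(31.5, spec), 1.035^-1.5, tolerance = 1e-12)
  expect_error(discount_factor(29, spec), "precedes the reference age")
})

test_that("discount factor is strictly decreasing in age for positive rates", {
  ages <- seq(30, 70, by = 0.5)
  f <- discount_factor(ages, discount_spec())
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
})

test_that("staff time is costed with weighting and supervision loading", {
  cfg <- staffing_config()
  band3 <- staff_rate("band3", 17.19, london_weighted = TRUE)
  expect_equal(staff_time_cost(60, band3, cfg), 17.19)
  consultant <- staff_rate("consultant", 139.73)
  # oracle: 139.73 * 45/60 = 104.7975, the printed clinic appointment
  expect_equal(staff_time_cost(45, consultant, cfg), 104.7975)
  counsellor <- staff_rate("counsellor", 55.54)
  # oracle: (55.54 + 139.73/12.5) * 0.75
  expect_equal(staff_time_cost(45, counsellor, cfg, consultant),
               (55.54 + 139.73 / 12.5) * 0.75)
  expect_equal(round(staff_time_cost(45, counsellor, cfg, consultant), 2),
               50.04)
  # weighting applied exactly once: an unweighted rate gets the 1.19
  raw <- staff_rate("consultant_raw", 139.73 / 1.19, london_weighted = FALSE)
  expect_equal(staff_time_cost(45, raw, cfg), 104.7975, tolerance = 1e-9)
  expect_error(staff_time_cost(-5, band3, cfg), "non-negative")
})

test_that("schedules expand on the start-inclusive end-exclusive grid", {
  pop <- surveillance_schedule("population", data.frame(
    modality = "mammography", unit_cost = 45.50,
    start_age = 50, end_age = 70, interval_years = 3))
  ev <- expand_schedule(pop)
  expect_equal(ev$age_at_event, c(50, 53, 56, 59, 62, 65, 68))
  expect_true(all(ev$unit_cost == 45.50))

  annual <- surveillance_schedule("higher", data.frame(
    modality = "mammography", unit_cost = 45.50,
    start_age = 40, end_age = 50, interval_years = 1))
  expect_equal(expand_schedule(annual)$age_at_event, 40:49)

  empty <- surveillance_schedule("population", data.frame(
    modality = character(), unit_cost = numeric(), start_age = numeric(),
    end_age = numeric(), interval_years = numeric()))
  expect_equal(nrow(expand_schedule(empty)), 0)

  expect_error(surveillance_schedule("higher", data.frame(
    modality = "mammography", unit_cost = 45.50,
    start_age = c(40, 45), end_age = c(50, 55),
    interval_years = c(1, 1))), "overlapping")
})

test_that("stream cost discounts only discountable events", {
  spec <- discount_spec()
  expect_equal(stream_cost(scheduled_events(), spec), 0)
  ev <- scheduled_events(c(40, 45, 50), 45.50, "mammography",
                         c(TRUE, TRUE, TRUE))
  expect_equal(stream_cost(ev, discount_spec(annual_rate = 0)), 3 * 45.50)
  # surgery in the presentation year: never discounted
  surgery <- scheduled_events(55, 6784.00, "mastectomy", FALSE)
  expect_equal(stream_cost(surgery, spec), 6784.00)
  # linearity in unit cost and additivity over disjoint sets
  ev2 <- ev; ev2$unit_cost <- 2 * ev2$unit_cost
  expect_equal(stream_cost(ev2, spec), 2 * stream_cost(ev, spec))
  expect_equal(stream_cost(rbind(ev, surgery), spec),
               stream_cost(ev, spec) + stream_cost(surgery, spec))
})

test_that("expected management cost reproduces intervention expectations", {
  spec <- discount_spec()
  sch <- default_schedules()
  ivs <- carrier_interventions(affected = FALSE)
  surv_only <- expected_management_cost("carrier", list(), spec, sch)
  full <- expected_management_cost("carrier", ivs, spec, sch)
  # oracles: 0.30 * 6784.00 and 0.60 * 3355.43
  expect_equal(full - surv_only, 0.30 * 6784.00 + 0.60 * 3355.43)
  zero <- list(intervention("none", 6784, 0))
  expect_equal(expected_management_cost("carrier", zero, spec, sch),
               surv_only)
  # affected ovarian: post-ovarian mastectomy expectation 0.69*0.05*6784
  iva <- carrier_interventions(affected = TRUE, cancer_type = "ovarian")
  masto <- iva[[which(vapply(iva, `[[`, character(1), "name") ==
                        "post-ovarian bilateral mastectomy")]]
  contrib <- masto$uptake_probability * masto$survival_scaling *
    masto$unit_cost
  expect_equal(contrib, 0.69 * 0.05 * 6784.00)
  expect_false(masto$discountable)
  expect_error(expected_management_cost("unknown-tier"), "unknown")
})

test_that("carrier schedule covers annual mammography 40-70 and MRI 30-50", {
  ev <- expand_schedule(default_schedules()$carrier)
  expect_equal(sum(ev$label == "mammography"), 30)
  expect_equal(sum(ev$label == "mri"), 20)
  expect_equal(range(ev$age_at_event[ev$label == "mri"]), c(30, 49))
})
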