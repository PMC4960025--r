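calibrated_labels <- function() {
  intersect(the_costs$label[the_costs$source == "calibrated"],
            unique(unlist(the_catalog$activities)))
}

test_that("calibration against published totals recovers shipped components", {
  res <- cmd_calibrate()
  expect_false(res$rank_deficient)
  shipped <- stats::setNames(the_costs$cost_gbp, the_costs$label)
  for (l in names(res$estimates)) {
    expect_lt(abs(res$estimates[l] - shipped[l]), 0.01, label = l)
  }
  # residuals confined to the 1p inconsistency in pathways 6 and 7
  expect_true(all(abs(res$residuals) <= 0.02))
  expect_true(all(abs(res$residuals[!names(res$residuals) %in%
                                      c("6", "7")]) < 0.005))
})

test_that("tier and carrier increments fall out of the calibrated estimates", {
  res <- cmd_calibrate()
  higher <- cost_lookup(the_costs, "surveillance_higher")
  expect_equal(round(higher - res$estimates["surveillance_moderate"], 2),
               c(surveillance_moderate = 49.51))
  expect_equal(round(res$estimates["carrier_management_unaffected"] -
                       res$estimates["surveillance_population"], 2),
               c(carrier_management_unaffected = 7329.68))
})

test_that("a fully determined synthetic system is recovered exactly", {
  inst <- perturb_cost_table(the_costs, the_catalog,
                             hidden_labels = c("brca_predictive_test",
                                               "gp_referral"),
                             noise_scale = 0, seed = 11)
  res <- solve_components(inst$problem)
  expect_false(res$rank_deficient)
  expect_equal(res$estimates[names(inst$truth$hidden)], inst$truth$hidden,
               tolerance = 1e-9)
  expect_true(all(abs(res$residuals) < 1e-9))
})

test_that("parameter recovery over random hidden subsets is exact at zero noise", {
  labels <- calibrated_labels()
  set.seed(42)
  for (rep in 1:5) {
    hide <- sample(labels, 3)
    inst <- perturb_cost_table(the_costs, the_catalog, hide,
                               noise_scale = 0, seed = rep)
    res <- solve_components(inst$problem)
    expect_true(all(abs(res$estimates[hide] - inst$truth$hidden[hide]) <=
                      0.005), label = paste(hide, collapse = "+"))
  }
})

test_that("bounded rounding noise degrades recovery gracefully", {
  inst <- perturb_cost_table(the_costs, the_catalog,
                             hidden_labels = "brca_predictive_test",
                             noise_scale = 0.005, seed = 7)
  res <- solve_components(inst$problem)
  expect_lt(abs(res$estimates["brca_predictive_test"] -
                  inst$truth$hidden["brca_predictive_test"]), 0.05)
})

test_that("structurally unidentifiable components are flagged, not imputed", {
  # designed degeneracy: a ghost component that rides along with every GP
  # referral has a design column identical to gp_referral's — only their sum
  # is identifiable
  cat2 <- the_catalog
  cat2$activities <- lapply(cat2$activities, function(a) {
    if ("gp_referral" %in% a) c(a, "ghost_component") else a
  })
  costs2 <- rbind(the_costs, the_costs[the_costs$label == "gp_referral", ])
  costs2$label[nrow(costs2)] <- "ghost_component"
  costs2$cost_gbp[nrow(costs2)] <- 10
  inst <- perturb_cost_table(costs2, cat2,
                             hidden_labels = c("gp_referral",
                                               "ghost_component"),
                             noise_scale = 0, seed = 1)
  res <- suppressWarnings(solve_components(inst$problem))
  expect_true(res$rank_deficient)
  expect_true(all(c("gp_referral", "ghost_component") %in%
                    res$unidentifiable))
  expect_true(all(is.na(res$estimates[res$unidentifiable])))
})

test_that("the affected pathway 2/3 split is inferred as 9/1", {
  split <- infer_affected_split(the_printed[as.character(1:10)],
                                narrative_affected, 2083.95)
  expect_equal(unname(split), c(9, 1))
  # endpoint: a target equal to the all-identified mean returns (10, 0)
  cnt <- narrative_affected
  cnt[c("2", "3")] <- c(10, 0)
  target <- sum(cnt * the_printed[names(cnt)]) / sum(cnt)
  expect_equal(unname(infer_affected_split(the_printed[as.character(1:10)],
                                           narrative_affected, target)),
               c(10, 0))
  # unattainable target at zero tolerance errors explicitly
  expect_error(infer_affected_split(the_printed[as.character(1:10)],
                                    narrative_affected, 2083.95, tol = 0),
               "no split attains")
})

test_that("negative component estimates raise a model-structure warning", {
  cat16 <- the_catalog[16, ]  # single constraint determines gp_referral
  totals <- c("16" = 100)     # below the known components: estimate < 0
  knowns <- stats::setNames(the_costs$cost_gbp, the_costs$label)
  knowns <- knowns[setdiff(intersect(names(knowns),
                                     unique(unlist(cat16$activities))),
                           "gp_referral")]
  prob <- calibration_problem(cat16, totals, knowns, "gp_referral")
  expect_warning(solve_components(prob), "negative component")
})
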