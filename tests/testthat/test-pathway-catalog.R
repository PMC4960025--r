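test_that("shipped catalog has 28 pathways partitioned 10/18", {
  expect_equal(nrow(the_catalog), 28)
  expect_equal(sum(the_catalog$affected), 10)
  expect_equal(sum(!the_catalog$affected), 18)
  expect_setequal(the_catalog$id, 1:28)
  expect_true(all(the_catalog$id[the_catalog$affected] <= 10))
})

test_that("catalog validation rejects missing or duplicate ids", {
  raw <- utils::read.csv(pathcost_file("pathways.csv"),
                         stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(raw[-6, ], f, row.names = FALSE)  # 27 rows
  expect_error(load_catalog(f), "exactly pathways 1-28")
  dup <- raw; dup$id[6] <- 5
  utils::write.csv(dup, f, row.names = FALSE)
  expect_error(load_catalog(f), "duplicate")
  unlink(f)
})

test_that("classification matches the published pathway structure", {
  expect_equal(classify(case_record(TRUE, "breast", eligible_for_test = TRUE,
                                    patient_decision = "accepts",
                                    test_performed = "full",
                                    test_result = "positive")), 1L)
  expect_equal(classify(case_record(FALSE, "none", "known_in_family",
                                    eligible_for_test = TRUE,
                                    patient_decision = "accepts",
                                    test_performed = "predictive",
                                    test_result = "positive")), 11L)
  expect_equal(classify(case_record(FALSE, "none", "none_known",
                                    eligible_for_test = TRUE,
                                    relative_pathway =
                                      "relative_full_test_negative",
                                    family_history_tier = "population")),
               21L)
})

test_that("inconsistent case records are rejected with named constraints", {
  expect_error(case_record(TRUE, "none"), "cancer_type")
  expect_error(case_record(TRUE, "breast", test_performed = "full",
                           test_result = "n/a"), "test_result")
  expect_error(case_record(TRUE, "breast", eligible_for_test = TRUE,
                           patient_decision = "declines",
                           test_performed = "full",
                           test_result = "negative"), "declining")
  expect_error(case_record(FALSE, "none", relative_pathway =
                             "relative_full_test_positive"),
               "eligib|predictive")
})

test_that("round trip: records generated from pathway k classify back to k", {
  for (k in 1:28) {
    expect_equal(classify(case_from_pathway(k)), k,
                 label = paste("pathway", k))
  }
})

test_that("classify is exhaustive and mutually exclusive over the consistent record space", {
  grid <- expand.grid(
    affected = c(TRUE, FALSE),
    cancer_type = c("breast", "ovarian", "none"),
    familial_mutation_status = c("none_known", "known_in_family",
                                 "family_tested_negative", "family_untested"),
    eligible_for_test = c(TRUE, FALSE),
    patient_decision = c("accepts", "declines", "n/a"),
    test_performed = c("full", "predictive", "none"),
    test_result = c("positive", "negative", "n/a"),
    relative_pathway = c("none", "relative_full_test_positive",
                         "relative_full_test_negative",
                         "intervening_relative_negative",
                         "relative_unavailable"),
    family_history_tier = c("population", "moderate", "higher"),
    stringsAsFactors = FALSE
  )
  seen <- integer(0)
  n_consistent <- 0
  for (i in seq_len(nrow(grid))) {
    rec <- tryCatch(do.call(case_record, as.list(grid[i, ])),
                    error = function(e) NULL)
    if (is.null(rec)) next
    id <- tryCatch(classify(rec), error = function(e) NA_integer_)
    if (is.na(id)) next  # residual inconsistency caught at classify time
    n_consistent <- n_consistent + 1
    expect_true(id %in% 1:28)
    seen <- union(seen, id)
  }
  expect_gt(n_consistent, 28)
  expect_setequal(seen, 1:28)  # every pathway reachable
})
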