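#' Load a pathway catalog
#'
#' The catalog encodes the 28 referral-to-management pathways of the service:
#' 10 for women affected by breast and/or ovarian cancer (referred through
#' oncology) and 18 for unaffected women with a family history (referred by
#' their GP).  Each row carries the ordered activity list used for itemized
#' costing, the testing route, the management assignment and the published
#' pathway total.
#'
#' @param path CSV definition file; defaults to the shipped catalog.
#' @return data.frame of class `pathway_catalog` with a list-column
#'   `activities`.
#' @export
load_catalog <- function(path = pathcost_file("pathways.csv")) {
  cat28 <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "affected", "description", "activities", "test_spec",
            "management_patient", "printed_total_gbp")
  miss <- setdiff(need, names(cat28))
  if (length(miss)) stop("pathway catalog missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cat28$id)) stop("duplicate pathway ids: ",
                                    paste(cat28$id[duplicated(cat28$id)],
                                          collapse = ", "))
  if (!setequal(cat28$id, 1:28)) {
    stop("catalog must define exactly pathways 1-28; got ", nrow(cat28),
         " rows with ids ", paste(range(cat28$id), collapse = "-"))
  }
  cat28 <- cat28[order(cat28$id), ]
  cat28$affected <- as.logical(cat28$affected)
  if (sum(cat28$affected) != 10 || sum(!cat28$affected) != 18) {
    stop("catalog must partition into 10 affected and 18 unaffected pathways")
  }
  cat28$activities <- strsplit(cat28$activities, "|", fixed = TRUE)
  cat28$printed_total_gbp <- as.numeric(cat28$printed_total_gbp)
  class(cat28) <- c("pathway_catalog", "data.frame")
  cat28
}

#' The shipped service catalog
#' @return the default 28-pathway catalog (see [load_catalog()]).
#' @export
rms_catalog <- function() load_catalog()

#' Named pathway id groups used in reporting
#'
#' `carrier_presenting` are pathways where the presenting patient is found to
#' carry a BRCA mutation; `full_test` where a full mutation screen is done in
#' the patient or a relative; `predictive` where a predictive test for a
#' known familial mutation is done; `relative_tested` where testing is
#' recommended in a relative of a presenting unaffected patient.
#'
#' @return named list of integer id vectors.
#' @export
pathway_groups <- function() {
  list(all = 1:28, affected = 1:10, unaffected = 11:28,
       carrier_presenting = c(1, 2, 11, 17),
       full_test = c(1, 6, 7, 17:21),
       predictive = c(2, 3, 11, 13, 25),
       relative_tested = 17:21,
       duplicate_cost_triples = list(c(14, 22, 27), c(15, 23, 26),
                                     c(16, 24, 28)))
}

case_levels <- list(
  cancer_type = c("breast", "ovarian", "both", "none"),
  familial_mutation_status = c("none_known", "known_in_family",
                               "family_tested_negative", "family_untested"),
  patient_decision = c("accepts", "declines", "n/a"),
  test_performed = c("full", "predictive", "none"),
  test_result = c("positive", "negative", "n/a"),
  relative_pathway = c("none", "relative_full_test_positive",
                       "relative_full_test_negative",
                       "intervening_relative_negative",
                       "relative_unavailable"),
  family_history_tier = c("population", "moderate", "higher")
)

#' Structured referral case description
#'
#' The structured input to [classify()]: who presents (affected or not),
#' what is known about the familial mutation, the testing route followed and
#' its result, any relative's testing route, and the family-history risk
#' tier.  The constructor validates internal consistency (e.g. a test result
#' requires a test, declining precludes one) and errors naming the violated
#' constraint.
#'
#' @param affected is the presenting woman affected by breast/ovarian cancer?
#' @param cancer_type `"breast"`, `"ovarian"`, `"both"`, or `"none"` (must be
#'   `"none"` iff unaffected).
#' @param familial_mutation_status one of `"none_known"`,
#'   `"known_in_family"`, `"family_tested_negative"`, `"family_untested"`.
#' @param eligible_for_test is BRCA testing recommended for the patient (or,
#'   for unaffected patients, in the family)?
#' @param patient_decision `"accepts"`, `"declines"`, or `"n/a"`.
#' @param test_performed `"full"`, `"predictive"`, or `"none"`.
#' @param test_result `"positive"`, `"negative"`, or `"n/a"`.
#' @param relative_pathway testing route followed by a relative, if any.
#' @param family_history_tier `"population"`, `"moderate"`, or `"higher"`.
#' @return an object of class `case_record`.
#' @export
case_record <- function(affected, cancer_type = if (affected) "breast" else "none",
                        familial_mutation_status = "none_known",
                        eligible_for_test = FALSE,
                        patient_decision = "n/a",
                        test_performed = "none", test_result = "n/a",
                        relative_pathway = "none",
                        family_history_tier = "population") {
  rec <- list(affected = isTRUE(affected),
              cancer_type = match.arg(cancer_type, case_levels$cancer_type),
              familial_mutation_status =
                match.arg(familial_mutation_status,
                          case_levels$familial_mutation_status),
              eligible_for_test = isTRUE(eligible_for_test),
              patient_decision = match.arg(patient_decision,
                                           case_levels$patient_decision),
              test_performed = match.arg(test_performed,
                                         case_levels$test_performed),
              test_result = match.arg(test_result, case_levels$test_result),
              relative_pathway = match.arg(relative_pathway,
                                           case_levels$relative_pathway),
              family_history_tier = match.arg(family_history_tier,
                                              case_levels$family_history_tier))
  viol <- case_violations(rec)
  if (length(viol)) stop("inconsistent case record: ",
                         paste(viol, collapse = "; "))
  structure(rec, class = "case_record")
}

# internal: list of violated consistency constraints (empty if consistent)
case_violations <- function(r) {
  v <- character()
  if (r$affected && r$cancer_type == "none")
    v <- c(v, "affected=TRUE requires a cancer_type")
  if (!r$affected && r$cancer_type != "none")
    v <- c(v, "unaffected requires cancer_type='none'")
  if ((r$test_performed == "none") != (r$test_result == "n/a"))
    v <- c(v, "test_result must be 'n/a' exactly when no test was performed")
  if (r$patient_decision == "declines" && r$test_performed != "none")
    v <- c(v, "a declining patient cannot have a test performed")
  if (r$test_performed != "none" && r$patient_decision != "accepts")
    v <- c(v, "a performed test requires patient_decision='accepts'")
  if (r$affected && r$relative_pathway != "none")
    v <- c(v, "relative testing routes apply only to unaffected patients")
  if (r$affected && r$familial_mutation_status == "known_in_family" &&
      r$test_performed != "predictive")
    v <- c(v, paste("an affected patient with a known familial mutation",
                    "follows the predictive-test route"))
  if (r$test_performed == "full" && !r$affected)
    v <- c(v, "full mutation screens are performed in affected individuals")
  if (r$affected && r$test_performed == "full" && !r$eligible_for_test)
    v <- c(v, "a full test requires eligibility")
  if (r$affected && r$eligible_for_test &&
      r$familial_mutation_status == "none_known" &&
      r$patient_decision == "declines" &&
      r$family_history_tier == "population")
    v <- c(v, "declined testing is managed at moderate or higher risk")
  if (r$affected && r$test_performed == "full" && r$test_result == "negative" &&
      r$family_history_tier == "population")
    v <- c(v, "a negative full screen is managed at moderate or higher risk")
  if (r$affected && r$eligible_for_test &&
      r$familial_mutation_status == "none_known" &&
      r$patient_decision == "accepts" && r$test_performed != "full")
    v <- c(v, "an eligible affected patient who accepts has a full screen")
  if (!r$affected && r$familial_mutation_status == "known_in_family" &&
      r$relative_pathway %in% c("relative_full_test_positive",
                                "relative_full_test_negative"))
    v <- c(v, paste("a known familial mutation precludes a fresh full screen",
                    "in a relative"))
  if (!r$affected && r$relative_pathway == "intervening_relative_negative" &&
      r$familial_mutation_status != "known_in_family")
    v <- c(v, "an intervening-relative chain requires a known familial mutation")
  if (!r$affected && r$familial_mutation_status == "known_in_family" &&
      r$relative_pathway == "none" && r$patient_decision == "accepts" &&
      r$test_performed != "predictive")
    v <- c(v, "predictive testing is the route for a known familial mutation")
  if (!r$affected &&
      r$relative_pathway %in% c("relative_full_test_negative",
                                "intervening_relative_negative",
                                "relative_unavailable") &&
      r$test_performed != "none")
    v <- c(v, "the patient is not tested unless a relative tests positive")
  if (!r$affected && r$relative_pathway == "relative_full_test_positive" &&
      r$test_performed != "predictive")
    v <- c(v, paste("a relative's positive full screen is followed by a",
                    "predictive test in the patient"))
  if (!r$affected && !r$eligible_for_test && r$relative_pathway != "none")
    v <- c(v, "relative testing routes require family eligibility")
  if (!r$affected && r$familial_mutation_status == "family_untested" &&
      !r$relative_pathway %in% c("none", "relative_unavailable"))
    v <- c(v, "family_untested is incompatible with a tested relative")
  if (!r$affected && r$familial_mutation_status == "family_tested_negative" &&
      r$relative_pathway != "none")
    v <- c(v, "previously tested-negative families have no fresh relative route")
  if (!r$affected && r$familial_mutation_status == "none_known" &&
      r$eligible_for_test && r$relative_pathway == "none")
    v <- c(v, paste("an eligible family with no known mutation must state the",
                    "relative route (tested, unavailable) or be recorded as",
                    "family_untested"))
  v
}

#' Classify a referral case onto its pathway
#'
#' Total, exhaustive and mutually exclusive over consistent case records:
#' every record constructed by [case_record()] maps to exactly one of the 28
#' pathway ids.
#'
#' @param case a [case_record()].
#' @return integer pathway id in 1..28.
#' @examples
#' classify(case_record(TRUE, "breast", eligible_for_test = TRUE,
#'                      patient_decision = "accepts", test_performed = "full",
#'                      test_result = "positive"))  # 1
#' @export
classify <- function(case) {
  stopifnot(inherits(case, "case_record"))
  r <- case
  tier3 <- function(pop, mod, high) {
    switch(r$family_history_tier, population = pop, moderate = mod,
           higher = high)
  }
  if (r$affected) {
    if (r$familial_mutation_status == "known_in_family") {
      return(if (r$test_result == "positive") 2L else 3L)
    }
    if (r$eligible_for_test) {
      if (r$patient_decision == "declines") {
        return(tier3(NA, 5L, 4L))
      }
      if (r$test_performed == "full") {
        if (r$test_result == "positive") return(1L)
        return(tier3(NA, 7L, 6L))
      }
      stop("inconsistent case record: eligible affected patient with no ",
           "decision recorded")
    }
    return(tier3(8L, 9L, 10L))
  }
  # unaffected
  if (r$familial_mutation_status == "known_in_family") {
    if (r$relative_pathway == "intervening_relative_negative") return(25L)
    if (r$patient_decision == "declines") return(12L)
    if (r$test_performed == "predictive") {
      return(if (r$test_result == "positive") 11L else 13L)
    }
    stop("inconsistent case record: known familial mutation with no ",
         "predictive-test route or decline recorded")
  }
  if (r$familial_mutation_status == "family_tested_negative") {
    return(tier3(28L, 26L, 27L))
  }
  if (r$familial_mutation_status == "family_untested") {
    return(tier3(24L, 23L, 22L))
  }
  # none_known
  if (!r$eligible_for_test) return(tier3(16L, 15L, 14L))
  if (r$relative_pathway == "relative_full_test_positive") {
    return(if (r$test_result == "positive") 17L else 18L)
  }
  if (r$relative_pathway == "relative_full_test_negative") {
    return(tier3(21L, 20L, 19L))
  }
  if (r$relative_pathway == "relative_unavailable") {
    return(tier3(24L, 23L, 22L))
  }
  stop("inconsistent case record: unclassifiable combination")
}

#' Canonical case record for a pathway
#'
#' Inverse of [classify()] up to fields the pathway does not constrain:
#' `classify(case_from_pathway(k)) == k` for every k.  Used by the synthetic
#' cohort generator.
#'
#' @param id pathway id in 1..28.
#' @return a [case_record()].
#' @export
case_from_pathway <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:28)
  cr <- function(...) case_record(...)
  switch(as.character(id),
    "1" = cr(TRUE, "breast", eligible_for_test = TRUE,
             patient_decision = "accepts", test_performed = "full",
             test_result = "positive", family_history_tier = "higher"),
    "2" = cr(TRUE, "breast", "known_in_family", TRUE, "accepts",
             "predictive", "positive", family_history_tier = "higher"),
    "3" = cr(TRUE, "breast", "known_in_family", TRUE, "accepts",
             "predictive", "negative", family_history_tier = "higher"),
    "4" = cr(TRUE, "breast", eligible_for_test = TRUE,
             patient_decision = "declines", family_history_tier = "higher"),
    "5" = cr(TRUE, "breast", eligible_for_test = TRUE,
             patient_decision = "declines", family_history_tier = "moderate"),
    "6" = cr(TRUE, "breast", eligible_for_test = TRUE,
             patient_decision = "accepts", test_performed = "full",
             test_result = "negative", family_history_tier = "higher"),
    "7" = cr(TRUE, "breast", eligible_for_test = TRUE,
             patient_decision = "accepts", test_performed = "full",
             test_result = "negative", family_history_tier = "moderate"),
    "8" = cr(TRUE, "breast", family_history_tier = "population"),
    "9" = cr(TRUE, "breast", family_history_tier = "moderate"),
    "10" = cr(TRUE, "breast", family_history_tier = "higher"),
    "11" = cr(FALSE, "none", "known_in_family", TRUE, "accepts",
              "predictive", "positive", family_history_tier = "higher"),
    "12" = cr(FALSE, "none", "known_in_family", TRUE, "declines",
              family_history_tier = "higher"),
    "13" = cr(FALSE, "none", "known_in_family", TRUE, "accepts",
              "predictive", "negative", family_history_tier = "higher"),
    "14" = cr(FALSE, family_history_tier = "higher"),
    "15" = cr(FALSE, family_history_tier = "moderate"),
    "16" = cr(FALSE, family_history_tier = "population"),
    "17" = cr(FALSE, "none", "none_known", TRUE, "accepts", "predictive",
              "positive", "relative_full_test_positive", "higher"),
    "18" = cr(FALSE, "none", "none_known", TRUE, "accepts", "predictive",
              "negative", "relative_full_test_positive", "higher"),
    "19" = cr(FALSE, "none", "none_known", TRUE,
              relative_pathway = "relative_full_test_negative",
              family_history_tier = "higher"),
    "20" = cr(FALSE, "none", "none_known", TRUE,
              relative_pathway = "relative_full_test_negative",
              family_history_tier = "moderate"),
    "21" = cr(FALSE, "none", "none_known", TRUE,
              relative_pathway = "relative_full_test_negative",
              family_history_tier = "population"),
    "22" = cr(FALSE, "none", "family_untested", TRUE,
              relative_pathway = "relative_unavailable",
              family_history_tier = "higher"),
    "23" = cr(FALSE, "none", "family_untested", TRUE,
              relative_pathway = "relative_unavailable",
              family_history_tier = "moderate"),
    "24" = cr(FALSE, "none", "family_untested", TRUE,
              relative_pathway = "relative_unavailable",
              family_history_tier = "population"),
    "25" = cr(FALSE, "none", "known_in_family", TRUE,
              relative_pathway = "intervening_relative_negative",
              family_history_tier = "population"),
    "26" = cr(FALSE, "none", "family_tested_negative",
              family_history_tier = "moderate"),
    "27" = cr(FALSE, "none", "family_tested_negative",
              family_history_tier = "higher"),
    "28" = cr(FALSE, "none", "family_tested_negative",
              family_history_tier = "population")
  )
}
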