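#' One-way sensitivity scenario
#'
#' The base case is 100% consultant-delivered, 100% face-to-face
#' appointments, a £540 full-test price, and London weighting on.  A scenario
#' overrides one (or more) of these.
#'
#' @param label scenario label.
#' @param test_price full BRCA test price override in GBP, or `NULL` for the
#'   table price.
#' @param consultant_fraction fraction of appointments delivered by a
#'   consultant (remainder by a supervised genetic counsellor).
#' @param face_to_face_fraction fraction of appointments in clinic
#'   (remainder by telephone).
#' @param london_weighting apply the 1.19 London staff weighting?
#' @return object of class `scenario`.
#' @export
scenario <- function(label = "scenario", test_price = NULL,
                     consultant_fraction = 1, face_to_face_fraction = 1,
                     london_weighting = TRUE) {
  for (f in c(consultant_fraction, face_to_face_fraction)) {
    if (is.na(f) || f < 0 || f > 1) {
      stop("appointment fractions must be in [0, 1], got ", f)
    }
  }
  if (!is.null(test_price) && !is.na(test_price)) {
    stopifnot(test_price >= 0)
  } else {
    test_price <- NULL
  }
  structure(list(label = label, test_price = test_price,
                 consultant_fraction = consultant_fraction,
                 face_to_face_fraction = face_to_face_fraction,
                 london_weighting = isTRUE(london_weighting)),
            class = "scenario")
}

#' Per-appointment substitution costs
#'
#' The consultant clinic appointment is priced in the unit-cost table
#' (45 minutes of consultant time, £104.80).  The counsellor appointment is
#' derived at the same duration from the salary table with the 1:12.5
#' consultant supervision loading.  The telephone appointment is a
#' configurable assumption (default: 20 minutes of consultant time) — the
#' published analysis does not price it.
#'
#' @param costs a [read_unit_costs()] table.
#' @param rates a [read_staff_rates()] table.
#' @param cfg a [staffing_config()].
#' @param appointment_minutes duration of a clinic appointment (default 45).
#' @param telephone_minutes consultant time per telephone appointment
#'   (default 20).
#' @return list with `consultant`, `counsellor`, `telephone` costs in GBP.
#' @export
appointment_costs <- function(costs = read_unit_costs(),
                              rates = read_staff_rates(),
                              cfg = staffing_config(),
                              appointment_minutes = 45,
                              telephone_minutes = 20) {
  rate <- function(band) {
    i <- match(band, rates$band_label)
    if (is.na(i)) stop("no staff rate for band '", band, "'")
    staff_rate(band, rates$hourly_rate_gbp[i], rates$london_weighted[i])
  }
  cons <- rate("consultant")
  couns <- rate("band8_genetic_counsellor")
  list(
    consultant = cost_lookup(costs, "clinic_appointment"),
    counsellor = staff_time_cost(appointment_minutes, couns, cfg,
                                 supervising_rate = cons),
    telephone = staff_time_cost(telephone_minutes, cons, cfg)
  )
}

#' Per-pathway sensitivity features
#'
#' Aggregates, over each pathway's activity list, the counts of full BRCA
#' tests, predictive tests and clinic appointments (including those bundled
#' in composite relative-loop rows) and the staff-time cost content in GBP.
#'
#' @param catalog a [load_catalog()] catalog.
#' @param costs a [read_unit_costs()] table.
#' @return data.frame with one row per pathway: `id`, `n_full_tests`,
#'   `n_predictive_tests`, `n_appointments`, `staff_gbp`.
#' @export
pathway_features <- function(catalog, costs = read_unit_costs()) {
  agg <- function(acts, col) sum(costs[[col]][match(acts, costs$label)])
  data.frame(
    id = catalog$id,
    n_full_tests = vapply(catalog$activities, agg, numeric(1),
                          col = "n_full_tests"),
    n_predictive_tests = vapply(catalog$activities, agg, numeric(1),
                                col = "n_predictive_tests"),
    n_appointments = vapply(catalog$activities, agg, numeric(1),
                            col = "n_appointments"),
    staff_gbp = vapply(catalog$activities, agg, numeric(1), col = "staff_gbp")
  )
}

#' Total service cost under a sensitivity scenario
#'
#' Recomputes per-pathway costs with the scenario overrides applied and sums
#' over the audit counts.  A test-price change moves every full-test
#' instance in the weighted cohort (in the shipped audit: 35 in affected
#' patients + 16 in relatives = 51).  Consultant/counsellor and
#' clinic/telephone mixes blend the per-appointment cost linearly across all
#' appointments.  Removing London weighting rescales staff-time-derived cost
#' content by 1/1.19.
#'
#' @param sc a [scenario()].
#' @param catalog a [load_catalog()] catalog.
#' @param costs a [read_unit_costs()] table.
#' @param counts an [audit_counts()] vector.
#' @param base_costs per-pathway base cost vector (default the published
#'   totals carried in the catalog).
#' @param appts per-appointment costs from [appointment_costs()].
#' @param cfg a [staffing_config()].
#' @return total service cost in GBP.
#' @export
apply_scenario <- function(sc, catalog = rms_catalog(),
                           costs = read_unit_costs(), counts = rms_audit(),
                           base_costs = pathway_costs(catalog, costs),
                           appts = appointment_costs(costs),
                           cfg = staffing_config()) {
  stopifnot(inherits(sc, "scenario"))
  ft <- pathway_features(catalog, costs)
  adj <- base_costs[as.character(ft$id)]
  if (!is.null(sc$test_price)) {
    base_price <- cost_lookup(costs, "brca_full_test")
    adj <- adj + ft$n_full_tests * (sc$test_price - base_price)
  }
  blended <- sc$face_to_face_fraction *
    (sc$consultant_fraction * appts$consultant +
       (1 - sc$consultant_fraction) * appts$counsellor) +
    (1 - sc$face_to_face_fraction) * appts$telephone
  adj <- adj + ft$n_appointments * (blended - appts$consultant)
  if (!sc$london_weighting) {
    staff <- ft$staff_gbp +
      ft$n_appointments * (blended - appts$consultant)
    adj <- adj - staff * (1 - 1 / cfg$london_weighting_factor)
  }
  service_total(stats::setNames(adj, ft$id), counts)
}

#' One-way sensitivity table
#'
#' @param scenarios list of [scenario()] objects; the base case (no
#'   overrides) is always reported first.
#' @param ... passed to [apply_scenario()].
#' @return data.frame with columns `label` and `total_gbp`.
#' @export
one_way_table <- function(scenarios = list(), ...) {
  base <- scenario("Base case")
  scenarios <- c(list(base),
                 Filter(function(s) !identical(s$label, base$label),
                        scenarios))
  data.frame(
    label = vapply(scenarios, `[[`, character(1), "label"),
    total_gbp = vapply(scenarios, apply_scenario, numeric(1), ...),
    stringsAsFactors = FALSE
  )
}

#' Read a scenario file
#' @param path CSV with columns `label`, `test_price`, `consultant_fraction`,
#'   `face_to_face_fraction`, `london_weighting`; defaults to the shipped
#'   scenario set mirroring the published sensitivity analysis.
#' @return list of [scenario()] objects.
#' @export
read_scenarios <- function(path = pathcost_file("scenarios.csv")) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(s)), function(i) {
    scenario(s$label[i],
             test_price = if (is.na(s$test_price[i])) NULL else s$test_price[i],
             consultant_fraction = s$consultant_fraction[i],
             face_to_face_fraction = s$face_to_face_fraction[i],
             london_weighting = s$london_weighting[i])
  })
}
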