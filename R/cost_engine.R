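#' Discounting specification
#'
#' Future costs (surveillance, hormone replacement therapy) are discounted at
#' a fixed annual rate relative to the age at which the woman presents to the
#' service.  The base case presents at age 30 and discounts at 3.5% per year;
#' risk-reducing surgery is costed in the year of presentation and is not
#' discounted.
#'
#' @param annual_rate annual discount rate as a fraction (default 0.035).
#' @param reference_age age in years at presentation, the time origin of the
#'   discount frame (default 30).
#' @return an object of class `discount_spec`.
#' @examples
#' discount_factor(40, discount_spec())  # 1.035^-10
#' @export
discount_spec <- function(annual_rate = 0.035, reference_age = 30) {
  stopifnot(is.numeric(annual_rate), length(annual_rate) == 1,
            annual_rate >= 0, annual_rate < 1,
            is.numeric(reference_age), length(reference_age) == 1,
            reference_age > 0)
  structure(list(annual_rate = annual_rate, reference_age = reference_age),
            class = "discount_spec")
}

#' Discount factor at a given age
#'
#' `(1 + rate)^-(age - reference_age)`.  Equals 1 at the reference age and is
#' strictly decreasing in age for positive rates.  Fractional ages are allowed
#' (18-monthly scans fall on half-year grid points).
#'
#' @param age_at_event age in years at which the cost is incurred; must not
#'   precede the reference age.
#' @param spec a [discount_spec()].
#' @return numeric vector of factors in (0, 1].
#' @export
discount_factor <- function(age_at_event, spec = discount_spec()) {
  stopifnot(inherits(spec, "discount_spec"), is.numeric(age_at_event))
  if (any(age_at_event < spec$reference_age)) {
    stop("event age (", paste(age_at_event[age_at_event < spec$reference_age],
                              collapse = ", "),
         ") precedes the reference age ", spec$reference_age)
  }
  (1 + spec$annual_rate)^(-(age_at_event - spec$reference_age))
}

#' Hourly staff rate
#'
#' @param band_label descriptive label, e.g. `"consultant"`.
#' @param hourly_rate cost per hour in GBP; must be positive.
#' @param london_weighted whether the rate already includes the London
#'   weighting multiplier (the shipped salary table does).
#' @return an object of class `staff_rate`.
#' @export
staff_rate <- function(band_label, hourly_rate, london_weighted = TRUE) {
  stopifnot(is.character(band_label), length(band_label) == 1,
            is.numeric(hourly_rate), length(hourly_rate) == 1, hourly_rate > 0)
  structure(list(band_label = band_label, hourly_rate = hourly_rate,
                 london_weighted = isTRUE(london_weighted)),
            class = "staff_rate")
}

#' Staffing configuration
#'
#' London weighting multiplies staff-time costs by 1.19; genetic counsellor
#' time carries consultant supervision at 1 hour of consultant time per
#' 12.5 hours of counsellor time.
#'
#' @param london_weighting_factor multiplier, at least 1 (default 1.19).
#' @param supervision_hours_per_counsellor_hour supervision loading ratio
#'   (default 1/12.5).
#' @return an object of class `staffing_config`.
#' @export
staffing_config <- function(london_weighting_factor = 1.19,
                            supervision_hours_per_counsellor_hour = 1 / 12.5) {
  stopifnot(london_weighting_factor >= 1,
            supervision_hours_per_counsellor_hour >= 0)
  structure(list(london_weighting_factor = london_weighting_factor,
                 supervision_hours_per_counsellor_hour =
                   supervision_hours_per_counsellor_hour),
            class = "staffing_config")
}

#' Cost of a block of staff time
#'
#' `(rate + supervision loading) * minutes / 60`, with the London weighting
#' applied exactly once to any rate not already weighted.  The supervision
#' loading adds `supervising_rate * ratio` per hour, as for genetic counsellor
#' clinics supervised by a consultant.
#'
#' @param minutes non-negative duration in minutes.
#' @param rate a [staff_rate()] for the member of staff delivering the time.
#' @param cfg a [staffing_config()].
#' @param supervising_rate optional [staff_rate()] providing supervision.
#' @return cost in GBP (full precision).
#' @examples
#' consultant <- staff_rate("consultant", 139.73)
#' staff_time_cost(45, consultant)  # 104.7975, printed as 104.80
#' @export
staff_time_cost <- function(minutes, rate, cfg = staffing_config(),
                            supervising_rate = NULL) {
  stopifnot(is.numeric(minutes), length(minutes) == 1,
            inherits(rate, "staff_rate"), inherits(cfg, "staffing_config"))
  if (minutes < 0) stop("minutes must be non-negative, got ", minutes)
  weight <- function(r) {
    r$hourly_rate * if (r$london_weighted) 1 else cfg$london_weighting_factor
  }
  hourly <- weight(rate)
  if (!is.null(supervising_rate)) {
    stopifnot(inherits(supervising_rate, "staff_rate"))
    hourly <- hourly +
      weight(supervising_rate) * cfg$supervision_hours_per_counsellor_hour
  }
  hourly * minutes / 60
}

#' Surveillance schedule for a risk tier
#'
#' A schedule is a set of repeating imaging segments, e.g. the mutation
#' carrier tier combines annual mammography from 40 to 70 with annual MRI
#' from 30 to 50.  Segments of the same modality must not overlap.
#'
#' @param tier one of `"population"`, `"moderate"`, `"higher"`, `"carrier"`.
#' @param segments data.frame with columns `modality`, `unit_cost`,
#'   `start_age`, `end_age`, `interval_years`.
#' @return an object of class `surveillance_schedule`.
#' @export
surveillance_schedule <- function(tier, segments) {
  tier <- match.arg(tier, c("population", "moderate", "higher", "carrier"))
  need <- c("modality", "unit_cost", "start_age", "end_age", "interval_years")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  if (nrow(segments)) {
    stopifnot(all(segments$start_age < segments$end_age),
              all(segments$interval_years > 0),
              all(segments$unit_cost >= 0))
    for (m in unique(segments$modality)) {
      s <- segments[segments$modality == m, , drop = FALSE]
      if (nrow(s) > 1) {
        s <- s[order(s$start_age), ]
        if (any(s$start_age[-1] < s$end_age[-nrow(s)])) {
          stop("overlapping segments for modality '", m, "'")
        }
      }
    }
  }
  structure(list(tier = tier, segments = segments),
            class = "surveillance_schedule")
}

#' Expand a schedule into dated events
#'
#' Events fall on the arithmetic grid `start, start + interval, ...` and the
#' segment end is exclusive (an event exactly at `end_age` is not generated).
#' Each event carries the modality unit cost and is discountable.
#'
#' @param schedule a [surveillance_schedule()].
#' @return data.frame with columns `age_at_event`, `unit_cost`, `label`,
#'   `discountable`, ordered by age.
#' @examples
#' pop <- surveillance_schedule("population", data.frame(
#'   modality = "mammography", unit_cost = 45.50,
#'   start_age = 50, end_age = 70, interval_years = 3))
#' expand_schedule(pop)$age_at_event  # 50 53 56 59 62 65 68
#' @export
expand_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "surveillance_schedule"))
  seg <- schedule$segments
  if (!nrow(seg)) return(scheduled_events())
  ev <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    s <- seg[i, ]
    n <- ceiling((s$end_age - s$start_age) / s$interval_years - 1e-9)
    ages <- s$start_age + s$interval_years * seq_len(n) - s$interval_years
    data.frame(age_at_event = ages, unit_cost = s$unit_cost,
               label = s$modality, discountable = TRUE,
               stringsAsFactors = FALSE)
  }))
  ev[order(ev$age_at_event, ev$label), , drop = FALSE]
}

#' Construct a table of dated cost events
#'
#' @param age_at_event ages in years (fractional allowed).
#' @param unit_cost costs in GBP.
#' @param label event labels.
#' @param discountable logical; risk-reducing surgery is `FALSE` (costed in
#'   the year of presentation).
#' @return data.frame of scheduled events.
#' @export
scheduled_events <- function(age_at_event = numeric(), unit_cost = numeric(),
                             label = character(), discountable = logical()) {
  data.frame(age_at_event = as.numeric(age_at_event),
             unit_cost = as.numeric(unit_cost),
             label = as.character(label),
             discountable = as.logical(discountable),
             stringsAsFactors = FALSE)
}

#' Present-value cost of a stream of dated events
#'
#' Discountable events contribute `unit_cost * discount_factor(age)`;
#' non-discountable events (surgery) contribute their full cost.
#'
#' @param events data.frame as from [expand_schedule()] or
#'   [scheduled_events()].
#' @param spec a [discount_spec()].
#' @return cost in GBP (full precision).
#' @export
stream_cost <- function(events, spec = discount_spec()) {
  stopifnot(is.data.frame(events))
  if (!nrow(events)) return(0)
  d <- events$discountable
  disc <- if (any(d)) {
    sum(events$unit_cost[d] * discount_factor(events$age_at_event[d], spec))
  } else 0
  disc + sum(events$unit_cost[!d])
}

#' Probabilistic management intervention
#'
#' @param name label, e.g. `"bilateral mastectomy"`.
#' @param unit_cost cost in GBP.
#' @param uptake_probability fraction of carriers taking up the intervention.
#' @param survival_scaling survival probability applied when the intervention
#'   is conditional on surviving to its timing (1 = unconditional).
#' @param discountable surgery is costed in the year of presentation and not
#'   discounted.
#' @param timing_age age in years at which the intervention occurs.
#' @return an object of class `intervention`.
#' @export
intervention <- function(name, unit_cost, uptake_probability,
                         survival_scaling = 1, discountable = FALSE,
                         timing_age = 30) {
  stopifnot(is.numeric(unit_cost), unit_cost >= 0,
            uptake_probability >= 0, uptake_probability <= 1,
            survival_scaling >= 0, survival_scaling <= 1)
  structure(list(name = name, unit_cost = unit_cost,
                 uptake_probability = uptake_probability,
                 survival_scaling = survival_scaling,
                 discountable = isTRUE(discountable),
                 timing_age = timing_age),
            class = "intervention")
}

#' Standard risk-reducing intervention set for a BRCA carrier
#'
#' Unaffected carriers: 30% uptake of bilateral mastectomy and 60% of
#' bilateral salpingo-oophorectomy, both in the presentation year
#' (undiscounted).  Affected carriers: management at or after 5 years from
#' presentation is scaled by the 5-year survival probability (0.70 breast,
#' 0.69 ovarian); 5% of ovarian carriers surviving to 5 years undergo
#' bilateral mastectomy then (undiscounted, per the surgery rule).
#'
#' @param affected is the carrier herself affected by cancer?
#' @param cancer_type `"breast"`, `"ovarian"` or `"none"`.
#' @param mastectomy_cost,bso_cost unit costs in GBP (defaults Table values
#'   6784.00 and 3355.43).
#' @param uptake_mastectomy,uptake_bso uptake fractions (defaults 0.30, 0.60).
#' @param survival_breast,survival_ovarian 5-year survival at age 40
#'   (defaults 0.70, 0.69).
#' @param post_ovarian_mastectomy_rate fraction of surviving ovarian carriers
#'   undergoing mastectomy at year 5 (default 0.05).
#' @param reference_age presentation age (default 30).
#' @return list of [intervention()] objects.
#' @export
carrier_interventions <- function(affected = FALSE, cancer_type = "none",
                                  mastectomy_cost = 6784.00,
                                  bso_cost = 3355.43,
                                  uptake_mastectomy = 0.30,
                                  uptake_bso = 0.60,
                                  survival_breast = 0.70,
                                  survival_ovarian = 0.69,
                                  post_ovarian_mastectomy_rate = 0.05,
                                  reference_age = 30) {
  cancer_type <- match.arg(cancer_type, c("none", "breast", "ovarian", "both"))
  if (!affected) {
    return(list(
      intervention("bilateral mastectomy", mastectomy_cost, uptake_mastectomy,
                   timing_age = reference_age),
      intervention("bilateral salpingo-oophorectomy", bso_cost, uptake_bso,
                   timing_age = reference_age)
    ))
  }
  surv <- switch(cancer_type, breast = survival_breast,
                 ovarian = survival_ovarian, both = survival_ovarian, 1)
  out <- list(
    intervention("bilateral salpingo-oophorectomy", bso_cost, uptake_bso,
                 survival_scaling = surv, timing_age = reference_age + 5)
  )
  if (cancer_type %in% c("ovarian", "both")) {
    out <- c(out, list(
      intervention("post-ovarian bilateral mastectomy", mastectomy_cost,
                   post_ovarian_mastectomy_rate, survival_scaling = surv,
                   timing_age = reference_age + 5)
    ))
  } else {
    out <- c(out, list(
      intervention("bilateral mastectomy", mastectomy_cost, uptake_mastectomy,
                   survival_scaling = surv, timing_age = reference_age + 5)
    ))
  }
  out
}

#' Expected carrier or tier management cost
#'
#' The discounted surveillance stream for the management tier plus, for
#' mutation carriers, the expectation over risk-reducing interventions:
#' `uptake * survival_scaling * unit_cost`, discounted only when the
#' intervention is marked discountable.
#'
#' @param tier management assignment: `"population"`, `"moderate"`,
#'   `"higher"` or `"carrier"`.
#' @param interventions list of [intervention()] (typically
#'   [carrier_interventions()]); ignored for non-carrier tiers.
#' @param spec a [discount_spec()].
#' @param schedules named list of [surveillance_schedule()] per tier, as from
#'   [default_schedules()].
#' @return cost in GBP (full precision).
#' @examples
#' # expectation for one intervention: 0.60 * 3355.43 = 2013.258
#' @export
expected_management_cost <- function(tier, interventions = list(),
                                     spec = discount_spec(),
                                     schedules = default_schedules()) {
  if (!tier %in% names(schedules)) {
    stop("unknown management tier '", tier, "'")
  }
  surv <- stream_cost(expand_schedule(schedules[[tier]]), spec)
  extra <- 0
  for (iv in interventions) {
    stopifnot(inherits(iv, "intervention"))
    df <- if (iv$discountable) discount_factor(iv$timing_age, spec) else 1
    extra <- extra + iv$uptake_probability * iv$survival_scaling *
      iv$unit_cost * df
  }
  surv + extra
}

#' Default surveillance schedules for the four risk tiers
#'
#' Population: 3-yearly mammography 50-70.  Moderate: annual mammography
#' 40-50 then the population programme.  Higher: annual mammography 40-50,
#' 18-monthly 50-60, then the population programme from 60.  Carrier: annual
#' mammography 40-70 plus annual MRI 30-50.  Segment ends are exclusive.
#'
#' @param mammography_cost,mri_cost unit costs in GBP (Table defaults 45.50
#'   and 145.88).
#' @return named list of [surveillance_schedule()] objects.
#' @export
default_schedules <- function(mammography_cost = 45.50, mri_cost = 145.88) {
  seg <- function(mod, cost, a, b, k) {
    data.frame(modality = mod, unit_cost = cost, start_age = a, end_age = b,
               interval_years = k, stringsAsFactors = FALSE)
  }
  list(
    population = surveillance_schedule("population",
      seg("mammography", mammography_cost, 50, 70, 3)),
    moderate = surveillance_schedule("moderate", rbind(
      seg("mammography", mammography_cost, 40, 50, 1),
      seg("mammography", mammography_cost, 50, 70, 3))),
    higher = surveillance_schedule("higher", rbind(
      seg("mammography", mammography_cost, 40, 50, 1),
      seg("mammography", mammography_cost, 50, 60, 1.5),
      seg("mammography", mammography_cost, 60, 70, 3))),
    carrier = surveillance_schedule("carrier", rbind(
      seg("mammography", mammography_cost, 40, 70, 1),
      seg("mri", mri_cost, 30, 50, 1)))
  )
}
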