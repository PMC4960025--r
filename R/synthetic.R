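#' Specification of a synthetic referral cohort
#'
#' @param n_patients cohort size.
#' @param pathway_probabilities 28-vector of pathway probabilities summing to
#'   1 (default: the shipped audit's empirical frequencies).
#' @param seed integer seed; recorded in every generated artifact.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        pathway_probabilities = audit_frequencies(),
                        seed = 1L) {
  stopifnot(n_patients >= 0, length(pathway_probabilities) == 28,
            all(pathway_probabilities >= 0))
  if (abs(sum(pathway_probabilities) - 1) > 1e-12) {
    stop("pathway probabilities must sum to 1 (got ",
         sum(pathway_probabilities), ")")
  }
  structure(list(n_patients = as.integer(n_patients),
                 pathway_probabilities = as.numeric(pathway_probabilities),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Empirical pathway frequencies of the shipped audit
#' @param counts an [audit_counts()] vector (default the shipped audit with
#'   pending tests allocated).
#' @return 28-vector of frequencies summing to 1.
#' @export
audit_frequencies <- function(counts = rms_audit()) {
  as.numeric(counts[as.character(1:28)]) / sum(counts)
}

#' Sample a synthetic referral cohort
#'
#' Draws patient pathways multinomially and renders each patient as a
#' consistent [case_record()] that [classify()] maps back to its source
#' pathway.  Bit-identical for a given seed.
#'
#' @param spec a [cohort_spec()].
#' @param catalog a [load_catalog()] catalog (for pathway descriptions).
#' @return list with `records` (data.frame, one row per patient, including
#'   the source `pathway_id`) and `truth` (list: `true_counts` as
#'   [audit_counts()], `spec`, `seed`).
#' @export
sample_cohort <- function(spec, catalog = rms_catalog()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  ids <- if (spec$n_patients > 0) {
    sample.int(28, spec$n_patients, replace = TRUE,
               prob = spec$pathway_probabilities)
  } else integer(0)
  records <- do.call(rbind, lapply(ids, function(k) {
    r <- case_from_pathway(k)
    data.frame(pathway_id = k, as.data.frame(unclass(r),
                                             stringsAsFactors = FALSE))
  }))
  if (is.null(records)) {
    records <- data.frame(pathway_id = integer(0))
  }
  counts <- audit_counts(
    stats::setNames(tabulate(ids, nbins = 28), 1:28),
    window_label = sprintf("synthetic cohort (seed %d)", spec$seed))
  list(records = records,
       truth = list(true_counts = counts, spec = spec, seed = spec$seed))
}

#' Generate a calibration test instance from a perturbed cost table
#'
#' Computes pathway totals from a ground-truth unit-cost table (optionally
#' adding bounded per-item rounding noise), then hides the named components.
#' The returned problem carries the totals and the surviving knowns; the
#' truth records the hidden values for parameter-recovery tests.
#'
#' @param costs ground-truth [read_unit_costs()] table.
#' @param catalog a [load_catalog()] catalog.
#' @param hidden_labels component labels to hide from the solver.
#' @param noise_scale half-width in GBP of uniform per-item noise added to
#'   each itemized amount before totalling (0 = exact totals).
#' @param seed integer seed for the noise draw.
#' @return list with `problem` (a [calibration_problem()]) and `truth`
#'   (named numeric: the hidden components' true costs, plus the seed).
#' @export
perturb_cost_table <- function(costs, catalog = rms_catalog(), hidden_labels,
                               noise_scale = 0, seed = 1L) {
  miss <- setdiff(hidden_labels, costs$label)
  if (length(miss)) stop("hidden label(s) not in cost table: ",
                         paste(miss, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  totals <- vapply(seq_len(nrow(catalog)), function(i) {
    amounts <- cost_lookup(costs, catalog$activities[[i]])
    if (noise_scale > 0) {
      amounts <- amounts + stats::runif(length(amounts), -noise_scale,
                                        noise_scale)
    }
    sum(amounts)
  }, numeric(1))
  names(totals) <- catalog$id
  all_costs <- stats::setNames(costs$cost_gbp, costs$label)
  used <- unique(unlist(catalog$activities))
  knowns <- all_costs[setdiff(intersect(names(all_costs), used),
                              hidden_labels)]
  list(problem = calibration_problem(catalog, totals, knowns,
                                     unknowns = hidden_labels),
       truth = list(hidden = all_costs[hidden_labels], seed = seed))
}
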