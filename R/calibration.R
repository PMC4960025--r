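#' Define a component-calibration problem
#'
#' The published analysis prints every pathway total but not every component
#' price (GP referral, predictive test, per-tier surveillance aggregates,
#' carrier-management bundles, relative-loop blocks).  Each pathway total is
#' linear in its components, so the unknowns can be recovered by
#' least-squares against the totals.
#'
#' @param catalog a [load_catalog()] catalog supplying the activity lists
#'   (the design matrix: activity multiplicities per pathway).
#' @param totals named per-pathway totals in GBP (default the published
#'   totals in the catalog).
#' @param knowns named numeric vector of known component costs.
#' @param unknowns character vector of labels to estimate; defaults to every
#'   activity label in the catalog not present in `knowns`.
#' @return object of class `calibration_problem`.
#' @export
calibration_problem <- function(catalog, totals = pathway_costs(catalog),
                                knowns, unknowns = NULL) {
  labels <- unique(unlist(catalog$activities))
  if (is.null(unknowns)) unknowns <- setdiff(labels, names(knowns))
  stray <- setdiff(labels, c(names(knowns), unknowns))
  if (length(stray)) stop("activity label(s) neither known nor declared ",
                          "unknown: ", paste(stray, collapse = ", "))
  A <- t(vapply(catalog$activities,
                function(a) vapply(labels, function(l) sum(a == l),
                                   numeric(1)),
                numeric(length(labels))))
  dimnames(A) <- list(catalog$id, labels)
  structure(list(A = A, totals = totals[as.character(catalog$id)],
                 knowns = knowns, unknowns = unknowns),
            class = "calibration_problem")
}

#' Least-squares recovery of unknown components
#'
#' Solves `A_unknown x ~ totals - A_known k` by QR least squares.  Rank
#' deficiency is reported, with the structurally unidentifiable unknowns
#' named (via the null space of the design); estimates for those are `NA`
#' rather than silently imputed.  Negative estimates trigger a
#' model-structure warning.
#'
#' @param problem a [calibration_problem()].
#' @param tol singular-value tolerance for rank detection.
#' @return object of class `calibration_result`: `estimates` (named,
#'   `NA` for unidentifiable), `residuals` (named by pathway id),
#'   `rank_deficient` flag, `unidentifiable` labels.
#' @export
solve_components <- function(problem, tol = 1e-8) {
  stopifnot(inherits(problem, "calibration_problem"))
  kn <- names(problem$knowns)
  Ak <- problem$A[, kn, drop = FALSE]
  Au <- problem$A[, problem$unknowns, drop = FALSE]
  b <- problem$totals - as.numeric(Ak %*% problem$knowns)
  if (!length(problem$unknowns)) {
    return(structure(list(estimates = numeric(0), residuals = b,
                          rank_deficient = FALSE,
                          unidentifiable = character(0)),
                     class = "calibration_result"))
  }
  sv <- svd(Au)
  rank <- sum(sv$d > tol * max(sv$d, 1))
  deficient <- rank < ncol(Au)
  unident <- character(0)
  est <- stats::setNames(rep(NA_real_, ncol(Au)), colnames(Au))
  if (deficient) {
    null_v <- sv$v[, (rank + 1):ncol(Au), drop = FALSE]
    unident <- colnames(Au)[rowSums(abs(null_v)) > tol]
    ident <- setdiff(colnames(Au), unident)
    if (length(ident)) {
      fit <- stats::lsfit(Au[, ident, drop = FALSE], b, intercept = FALSE)
      est[ident] <- fit$coefficients
      resid <- b - as.numeric(Au[, ident, drop = FALSE] %*% est[ident])
    } else {
      resid <- b
    }
  } else {
    est[] <- qr.coef(qr(Au), b)
    resid <- b - as.numeric(Au %*% est)
  }
  neg <- names(est)[!is.na(est) & est < -1e-9]
  if (length(neg)) {
    warning("negative component estimate(s) — model-structure issue: ",
            paste(neg, collapse = ", "))
  }
  structure(list(estimates = est,
                 residuals = stats::setNames(resid, rownames(problem$A)),
                 rank_deficient = deficient, unidentifiable = unident),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result (", if (x$rank_deficient) "rank deficient"
      else "full rank", ")\n", sep = "")
  if (length(x$estimates)) {
    for (l in names(x$estimates)) {
      cat(sprintf("  %-32s %s\n", l,
                  if (is.na(x$estimates[l])) "unidentifiable"
                  else fmt_gbp(x$estimates[l])))
    }
  }
  cat("max |residual|:", fmt_gbp(max(abs(x$residuals))), "\n")
  invisible(x)
}

#' Infer the unpublished pathway 2/3 split of the affected audit cohort
#'
#' Ten affected women had a known familial BRCA mutation; the audit
#' narrative does not print how many tested positive (pathway 2) versus
#' negative (pathway 3).  The published affected weighted-average cost pins
#' the split: brute-force all 11 integer splits and return the unique
#' minimiser of the distance to the target mean.
#'
#' @param affected_costs named costs for pathways 1..10.
#' @param narrative_counts named counts for pathways 1..10 with `NA` at the
#'   two ids to split.
#' @param target_weighted_mean published affected weighted mean in GBP.
#' @param n_to_split total count to distribute (default 10).
#' @param split_ids the two pathway ids receiving the split (default 2, 3).
#' @param tol acceptance tolerance on the achieved mean in GBP (default
#'   0.005, i.e. the printed half-penny).
#' @return integer vector `c(n_identified, n_not_identified)`.
#' @export
infer_affected_split <- function(affected_costs, narrative_counts,
                                 target_weighted_mean, n_to_split = 10,
                                 split_ids = c(2, 3), tol = 0.005) {
  ids <- as.character(split_ids)
  stopifnot(all(ids %in% names(affected_costs)))
  cnt <- narrative_counts
  gaps <- vapply(0:n_to_split, function(s) {
    cnt[ids] <- c(s, n_to_split - s)
    abs(sum(cnt * affected_costs[names(cnt)]) / sum(cnt) -
          target_weighted_mean)
  }, numeric(1))
  best <- which(gaps == min(gaps))
  if (length(best) > 1) {
    stop("tie between splits ", paste(best - 1, collapse = " and "),
         " at distance ", fmt_gbp(min(gaps)))
  }
  if (min(gaps) > tol) {
    stop("no split attains the target mean within ", tol,
         " (best distance ", format(min(gaps)), ")")
  }
  c(n_identified = best - 1L, n_not_identified = n_to_split - (best - 1L))
}
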