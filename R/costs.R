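#' Read a unit-cost table
#'
#' The table maps activity labels to 2013 GBP unit costs.  Beyond `label`,
#' `cost_gbp`, `category` and `source`, the shipped table carries sensitivity
#' metadata per row: the staff-time content in GBP (`staff_gbp`, rescaled
#' when London weighting is toggled), and the number of clinic appointments,
#' full BRCA tests and predictive tests contained in the row
#' (`n_appointments`, `n_full_tests`, `n_predictive_tests`) — non-zero for
#' composite rows that bundle a relative's testing loop.
#'
#' @param path CSV file; defaults to the shipped table reproducing the
#'   printed unit costs plus components calibrated from printed pathway
#'   totals (rows with `source == "calibrated"`).
#' @return data.frame of class `unit_cost_table`.
#' @export
read_unit_costs <- function(path = pathcost_file("unit_costs.csv")) {
  uc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "cost_gbp", "category", "source")
  miss <- setdiff(need, names(uc))
  if (length(miss)) stop("unit-cost table missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("staff_gbp", "n_appointments", "n_full_tests",
                "n_predictive_tests")) {
    if (!col %in% names(uc)) uc[[col]] <- 0
  }
  uc$cost_gbp <- as.numeric(uc$cost_gbp)
  bad <- which(is.na(uc$cost_gbp) | uc$cost_gbp < 0)
  if (length(bad)) stop("malformed cost in row ", bad[1], " (label '",
                        uc$label[bad[1]], "')")
  if (anyDuplicated(uc$label)) stop("duplicate unit-cost labels: ",
                                    paste(unique(uc$label[duplicated(uc$label)]),
                                          collapse = ", "))
  class(uc) <- c("unit_cost_table", "data.frame")
  uc
}

#' Path to a shipped fixture file
#' @param file file name under the package's `extdata` directory.
#' @return absolute path.
#' @export
pathcost_file <- function(file) {
  p <- system.file("extdata", file, package = "pathcost")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Look up unit costs by label
#' @param costs a [read_unit_costs()] table.
#' @param labels character vector of activity labels.
#' @return numeric costs in GBP, in input order.
#' @export
cost_lookup <- function(costs, labels) {
  i <- match(labels, costs$label)
  if (anyNA(i)) stop("no unit cost for activity: ",
                     paste(unique(labels[is.na(i)]), collapse = ", "))
  costs$cost_gbp[i]
}

#' Read the staff salary table
#' @param path CSV file; defaults to the shipped London-weighted 2013 rates.
#' @return data.frame with `band_label`, `hourly_rate_gbp`, `london_weighted`.
#' @export
read_staff_rates <- function(path = pathcost_file("staff_rates.csv")) {
  sr <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("band_label", "hourly_rate_gbp", "london_weighted") %in%
                  names(sr)))
  sr
}

#' Itemized cost of one patient pathway
#'
#' Walks the pathway's ordered activity list, pricing each activity from the
#' unit-cost table.  The total is the full-precision sum of the items;
#' rounding to pennies is presentation only, so itemized totals may differ
#' from per-item-rounded printed totals by up to £0.02.
#'
#' @param pathway a single-row subset of a [load_catalog()] catalog, or a
#'   list with elements `id` and `activities` (character vector of labels).
#' @param costs a [read_unit_costs()] table.
#' @return object of class `pathway_cost`: list with `pathway_id`, `items`
#'   (data.frame label/amount/category) and `total`.
#' @examples
#' \dontrun{
#' pc <- pathway_cost(rms_catalog()[6, ], read_unit_costs())
#' pc$total       # 1630.97 at full precision; printed total 1630.96
#' nrow(pc$items) # 18
#' }
#' @export
pathway_cost <- function(pathway, costs) {
  if (is.data.frame(pathway)) {
    stopifnot(nrow(pathway) == 1)
    pathway <- list(id = pathway$id, activities = pathway$activities[[1]])
  }
  acts <- pathway$activities
  if (!length(acts)) {
    items <- data.frame(label = character(), amount = numeric(),
                        category = character(), stringsAsFactors = FALSE)
  } else {
    amounts <- cost_lookup(costs, acts)
    items <- data.frame(label = acts, amount = amounts,
                        category = costs$category[match(acts, costs$label)],
                        stringsAsFactors = FALSE)
  }
  structure(list(pathway_id = pathway$id, items = items,
                 total = sum(items$amount)),
            class = "pathway_cost")
}

#' @export
print.pathway_cost <- function(x, ...) {
  cat("Pathway", x$pathway_id, "—", nrow(x$items), "items\n")
  if (nrow(x$items)) {
    it <- x$items
    it$amount <- fmt_gbp(it$amount)
    print(it, row.names = FALSE)
  }
  cat("Total:", fmt_gbp(x$total), "\n")
  invisible(x)
}

#' Per-pathway cost vector for a whole catalog
#'
#' @param catalog a [load_catalog()] catalog.
#' @param costs a [read_unit_costs()] table (used when `source="computed"`).
#' @param source `"printed"` returns the published pathway totals carried in
#'   the catalog (the canonical values used for audit weighting and
#'   sensitivity analysis); `"computed"` re-derives each total from the
#'   activity itemization (agrees within £0.02 per-item rounding).
#' @return named numeric vector, names = pathway ids.
#' @export
pathway_costs <- function(catalog, costs = read_unit_costs(),
                          source = c("printed", "computed")) {
  source <- match.arg(source)
  v <- if (source == "printed") {
    catalog$printed_total_gbp
  } else {
    vapply(seq_len(nrow(catalog)),
           function(i) pathway_cost(catalog[i, ], costs)$total, numeric(1))
  }
  stats::setNames(v, catalog$id)
}
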