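#' Format pounds sterling for display
#'
#' Money is held at full double precision throughout the package; rounding to
#' pennies happens only at presentation.  All amounts are 2013 GBP.
#'
#' @param x numeric vector of amounts in pounds.
#' @param symbol prepend a pound sign?
#' @return character vector, penny precision.
#' @examples
#' fmt_gbp(1630.965)   # "£1630.97"
#' @export
fmt_gbp <- function(x, symbol = TRUE) {
  stopifnot(is.numeric(x))
  paste0(if (symbol) "£" else "", formatC(round(x, 2), format = "f", digits = 2))
}

#' Round to pennies (presentation only)
#' @param x numeric amounts in pounds.
#' @return numeric, rounded to 2 decimal places.
#' @export
round_gbp <- function(x) round(x, 2)

# internal: serialize money (or any numeric) as a decimal string so JSON
# round-trips are penny-exact; full precision retained for fractional counts.
money_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- formatC(v, format = "f", digits = 10)
    s <- sub("0+$", "", s)
    sub("\\.$", ".0", s)
  }, character(1))
}

money_num <- function(s) as.numeric(s)
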