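# Type A/B uncertainty bookkeeping.

#' Load the packaged uncertainty budget
#'
#' Component-wise k = 1 percent uncertainties for the three headline
#' quantities (dose rate at 0.10 cm and 1.0 cm on the transverse axis, air
#' kerma rate at 10 cm).  "Dynamic source design" is a stated maximum
#' lateral-shift bound rather than a standard error; it is nevertheless
#' combined in quadrature like the other components, and flagged by the
#' `is_bound` column.  Components tagged `manufacturing` are excluded when
#' comparing Monte Carlo calculations with each other.
#'
#' @param file optional CSV overriding the packaged budget.
#' @return data.frame with component, type, quantity, percent,
#'   manufacturing, is_bound.
#' @export
uncertaintyBudget <- function(file = NULL) {
  if (is.null(file)) file <- .extdata("uncertainty", "uncertainty_budget.csv")
  b <- read.csv(file, comment.char = "#")
  need <- c("component", "type", "quantity", "percent")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("budget file lacks column: ", miss[1])
  b
}

#' Combine uncertainty components in quadrature
#'
#' \eqn{\sqrt{\sum_i u_i^2}}, the total k = 1 uncertainty.
#'
#' @param percents numeric vector of k = 1 percent components.
#' @param digits decimals for the display rounding (the returned value is
#'   unrounded; `combinedDisplay` applies the rounding).
#' @return total percent (k = 1).
#' @export
combineQuadrature <- function(percents, digits = 2) {
  if (!length(percents)) stop("no uncertainty components supplied")
  if (any(percents < 0)) stop("uncertainty components must be >= 0")
  sqrt(sum(percents^2))
}

#' @rdname combineQuadrature
#' @export
combinedDisplay <- function(percents, digits = 2) {
  round(combineQuadrature(percents), digits)
}

#' Total uncertainty of a quantity from the budget
#'
#' @param quantity one of the budget's quantity tags, e.g. `"D(1.0cm)"`.
#' @param budget a budget data.frame (defaults to the packaged one).
#' @param excludeManufacturing drop the source/capsule-geometry and dynamic
#'   source-design components (the MC-to-MC comparison convention).
#' @param digits display rounding.
#' @return total percent (k = 1), rounded for display.
#' @export
totalUncertainty <- function(quantity, budget = uncertaintyBudget(),
                             excludeManufacturing = FALSE, digits = 2) {
  rows <- budget[budget$quantity == quantity, ]
  if (!nrow(rows)) stop("unknown quantity tag: ", quantity)
  if (excludeManufacturing && "manufacturing" %in% names(rows))
    rows <- rows[!rows$manufacturing, ]
  combinedDisplay(rows$percent, digits)
}
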