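# Trapezoidal integral of piecewise-linear samples.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Interpolated learning curve over the randomization period
#'
#' Builds a daily piecewise-linear trajectory from visit measurements:
#' values are linearly interpolated between visits, interior missing visits
#' are bridged by interpolation between the flanking non-missing visits, and
#' missing values at the boundaries are carried flat from the nearest
#' non-missing visit (interpolation is specified between visits; beyond the
#' outermost observations the curve is held constant).
#'
#' @param visit_days Numeric vector of visit days.
#' @param values Measurements at those days, `NA` for missing.
#' @param span Day range covered by the curve (default `c(0, 84)`, first fit
#'   to +12 weeks).
#' @return An object of class `learning_curve`: list with `day` (integer grid
#'   over `span`), `value`, and the non-missing `knots`.
#' @examples
#' lc <- learning_curve(c(0, 28, 42, 56), c(0, 28, NA, 56))
#' lc$value[lc$day == 42] # 42, bridged linearly across the missing visit
#' @export
learning_curve <- function(visit_days, values, span = c(0, 84)) {
  stopifnot(length(visit_days) == length(values), length(span) == 2L)
  keep <- !is.na(values) & !is.na(visit_days)
  if (sum(keep) < 2L) {
    stop("a learning curve needs at least 2 non-missing visits")
  }
  d <- as.numeric(visit_days)[keep]
  v <- as.numeric(values)[keep]
  o <- order(d)
  d <- d[o]; v <- v[o]
  if (any(diff(d) == 0)) stop("duplicate visit days")
  grid <- seq(span[1L], span[2L])
  out <- stats::approx(d, v, xout = grid, method = "linear", rule = 2)$y
  structure(list(day = grid, value = out,
                 knots = data.frame(visit_day = d, value = v)),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve: days %d-%d, %d visit knots, begin %.2f, end %.2f\n",
              min(x$day), max(x$day), nrow(x$knots),
              x$value[1L], x$value[length(x$value)]))
  invisible(x)
}

#' Summary parameters of a learning curve
#'
#' * `begin`: curve value at the first day of the span (result at first fit);
#' * `end`: value at the last day (result after three months for the default
#'   span);
#' * `auc`: area between curve and axis over the span (trapezoidal integral,
#'   units x days);
#' * `learning_rate`: average daily improvement over the first
#'   `rate_span` days, `(value(rate_span) - value(0)) / rate_span`
#'   (units/day; reported for CNC).
#'
#' @param curve A [learning_curve()].
#' @param rate_span Days over which the learning rate is taken (default 28,
#'   the first month).
#' @return An object of class `curve_params`: list with `begin`, `end`, `auc`,
#'   `learning_rate`.
#' @examples
#' cp <- curve_params(learning_curve(c(0, 84), c(0, 84)))
#' cp$auc # 3528, the triangle area
#' @export
curve_params <- function(curve, rate_span = 28) {
  stopifnot(inherits(curve, "learning_curve"))
  first <- curve$value[1L]
  last <- curve$value[length(curve$value)]
  at_rate <- curve$value[match(curve$day[1L] + rate_span, curve$day)]
  if (is.na(at_rate)) stop("rate_span falls outside the curve span")
  structure(list(begin = first, end = last,
                 auc = trapz(curve$day, curve$value),
                 learning_rate = (at_rate - first) / rate_span),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf("Curve parameters: begin %.2f, end %.2f, AUC %.1f, learning rate %.3f/day\n",
              x$begin, x$end, x$auc, x$learning_rate))
  invisible(x)
}
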