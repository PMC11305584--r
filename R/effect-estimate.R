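#' Effect measures
#'
#' Effect estimates are one of five measures: odds ratio (\code{"OR"}),
#' relative risk (\code{"RR"}), hazard ratio (\code{"HR"}) and incidence rate
#' ratio (\code{"IRR"}) are strictly positive ratio measures analysed on the
#' natural-log scale; the objective response rate (\code{"ORR"}) is a
#' proportion in [0, 1] from uncontrolled (typically phase 1 oncology) trials.
#'
#' @name effect-measures
#' @keywords internal
NULL

RATIO_MEASURES <- c("OR", "RR", "HR", "IRR")
EFFECT_MEASURES <- c(RATIO_MEASURES, "ORR")

#' Is a measure a ratio measure?
#'
#' @param measure character vector of measure codes.
#' @return logical: \code{TRUE} for OR/RR/HR/IRR, \code{FALSE} for ORR.
#' @export
is_ratio_measure <- function(measure) {
  measure <- toupper(measure)
  if (!all(measure %in% EFFECT_MEASURES)) {
    stop("unknown effect measure: ",
         paste(setdiff(measure, EFFECT_MEASURES), collapse = ", "))
  }
  measure %in% RATIO_MEASURES
}

#' Construct an effect estimate
#'
#' Bundles a point estimate with its confidence interval and measure kind.
#' Ratio measures must have a strictly positive lower bound; ORR estimates
#' must lie within [0, 1]. The point must lie inside the interval.
#'
#' @param point point estimate on the measure scale.
#' @param lo,hi confidence interval bounds.
#' @param measure one of \code{"OR"}, \code{"RR"}, \code{"HR"}, \code{"IRR"},
#'   \code{"ORR"}.
#' @param level confidence level in (0, 1); default 0.95.
#' @return an object of class \code{"effect_estimate"}.
#' @examples
#' effect_estimate(0.69, 0.55, 0.87, "HR")
#' @export
effect_estimate <- function(point, lo, hi, measure = c("OR", "RR", "HR", "IRR", "ORR"),
                            level = 0.95) {
  measure <- toupper(measure)[1]
  if (!measure %in% EFFECT_MEASURES) {
    stop("unknown effect measure: ", measure)
  }
  vals <- c(point = point, lo = lo, hi = hi)
  if (!all(is.finite(vals))) {
    stop("effect estimate values must be finite numbers")
  }
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    stop("'level' must be a single probability in (0, 1)")
  }
  if (lo > point || point > hi) {
    stop(sprintf("interval must contain the point estimate (lo <= point <= hi), got %g [%g, %g]",
                 point, lo, hi))
  }
  if (is_ratio_measure(measure)) {
    if (lo <= 0) stop("ratio measures require a strictly positive lower bound")
  } else {
    if (lo < 0 || hi > 1) stop("ORR estimates must lie within [0, 1]")
  }
  structure(list(measure = measure, point = point, lo = lo, hi = hi, level = level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s %s [%s, %s] (%d%% CI)\n", x$measure,
              format(x$point, digits = digits), format(x$lo, digits = digits),
              format(x$hi, digits = digits), round(100 * x$level)))
  invisible(x)
}

#' @export
as.numeric.effect_estimate <- function(x, ...) {
  c(point = x$point, lo = x$lo, hi = x$hi)
}

# interval extraction shared by the overlap/containment helpers
interval_bounds <- function(x) {
  if (inherits(x, "effect_estimate")) return(c(x$lo, x$hi))
  if (is.numeric(x) && length(x) == 2L) {
    if (x[1] > x[2]) stop("interval lower bound exceeds upper bound")
    return(as.numeric(x))
  }
  stop("expected an effect_estimate or a numeric vector c(lo, hi)")
}
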