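# CI-width divisor for a 95% interval: kept literally as 3.92 (= 2 * 1.96),
# the conventional reconstruction constant, rather than 2 * qnorm(0.975).
CI_WIDTH_DIVISOR <- 3.92

#' Standard error reconstructed from a printed confidence interval
#'
#' For a ratio measure reported as point [lo, hi] at the 95% level, the
#' log-scale standard error is (ln hi - ln lo) / 3.92. This is the standard
#' reconstruction used when only the published interval is available.
#'
#' @param estimate an \code{\link{effect_estimate}} with a ratio measure.
#' @return the standard error of the log effect (a positive scalar).
#' @examples
#' se_from_ci(effect_estimate(0.66, 0.59, 0.74, "RR"))
#' @export
se_from_ci <- function(estimate) {
  stopifnot(inherits(estimate, "effect_estimate"))
  if (!is_ratio_measure(estimate$measure)) {
    stop("standard errors from CIs are defined for ratio measures only, not ORR")
  }
  if (abs(estimate$level - 0.95) > 1e-8) {
    stop("CI reconstruction assumes a 95% interval")
  }
  if (estimate$lo == estimate$hi) {
    stop("degenerate interval (lo == hi): standard error is zero/undefined")
  }
  (log(estimate$hi) - log(estimate$lo)) / CI_WIDTH_DIVISOR
}

#' Two-sided p-value reconstructed from a point estimate and its CI
#'
#' Works on the natural-log scale: z = ln(point) / se, with the standard
#' error from \code{\link{se_from_ci}}, and p = 2 * (1 - Phi(|z|)). Up to
#' rounding of the printed bounds, p < 0.05 exactly when the 95% CI
#' excludes 1.
#'
#' @inheritParams se_from_ci
#' @return an object of class \code{"log_scale_summary"}: a list with
#'   \code{log_point}, \code{se}, \code{z} and \code{p}.
#' @examples
#' p_from_estimate(effect_estimate(0.96, 0.85, 1.08, "IRR"))$p  # ~0.50
#' @export
p_from_estimate <- function(estimate) {
  se <- se_from_ci(estimate)
  log_point <- log(estimate$point)
  z <- log_point / se
  structure(list(log_point = log_point, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "log_scale_summary")
}

#' @export
print.log_scale_summary <- function(x, digits = 4, ...) {
  cat(sprintf("log effect %s (SE %s), z = %s, two-sided p = %s\n",
              format(x$log_point, digits = digits), format(x$se, digits = digits),
              format(x$z, digits = digits), format(x$p, digits = digits)))
  invisible(x)
}

check_counts <- function(successes, n) {
  if (!(length(successes) == 1L && length(n) == 1L)) stop("counts must be scalars")
  if (n < 1) stop("undefined rate: n must be at least 1")
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  if (successes != round(successes) || n != round(n)) stop("counts must be integers")
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n counts with 0 <= successes <= n, n >= 1.
#' @param level confidence level, default 0.95.
#' @return named numeric vector \code{c(lo, hi)}.
#' @examples
#' round(100 * wilson_interval(20, 24))  # [64, 93]
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  check_counts(successes, n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # boundary cases are exact (0 and 1 algebraically); avoid float residue
  lo <- if (successes == 0) 0 else max(0, centre - half)
  hi <- if (successes == n) 1 else min(1, centre + half)
  c(lo = lo, hi = hi)
}

#' Wald (normal approximation) interval for a binomial proportion
#'
#' p +/- z * sqrt(p (1 - p) / n), truncated to [0, 1].
#'
#' @inheritParams wilson_interval
#' @return named numeric vector \code{c(lo, hi)}.
#' @export
wald_interval <- function(successes, n, level = 0.95) {
  check_counts(successes, n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  half <- z * sqrt(p * (1 - p) / n)
  c(lo = max(0, p - half), hi = min(1, p + half))
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' Exact beta-quantile bounds; lo = 0 when successes = 0 and hi = 1 when
#' successes = n. Coverage is at least the nominal level for every true
#' proportion.
#'
#' @inheritParams wilson_interval
#' @return named numeric vector \code{c(lo, hi)}.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  check_counts(successes, n)
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Objective response rate with exact confidence interval
#'
#' Builds an ORR effect estimate from responder counts, with a 95%
#' Clopper-Pearson interval -- the construction used when response rates
#' must be computed manually from reported counts.
#'
#' @param responders,n counts with 0 <= responders <= n, n >= 1.
#' @return an \code{\link{effect_estimate}} with measure \code{"ORR"}.
#' @export
orr_from_counts <- function(responders, n) {
  check_counts(responders, n)
  ci <- clopper_pearson(responders, n, 0.95)
  effect_estimate(responders / n, ci[["lo"]], ci[["hi"]], "ORR")
}

#' Odds or risk ratio from a 2x2 table with log-scale Wald interval
#'
#' Computes OR = (a d) / (b c) or RR = (a / n1) / (c / n2) from event counts
#' in two arms, with the standard log-scale standard errors
#' (OR: sqrt(1/a + 1/b + 1/c + 1/d); RR: sqrt(1/a - 1/n1 + 1/c - 1/n2)).
#' No continuity correction is applied: any zero cell that makes the SE
#' undefined is an error, and callers wanting a correction must add it to
#' the counts explicitly.
#'
#' @param events_a,total_a events and total in the first arm.
#' @param events_b,total_b events and total in the second arm.
#' @param measure \code{"OR"} or \code{"RR"}.
#' @param level confidence level for the interval.
#' @return an \code{\link{effect_estimate}}.
#' @examples
#' ratio_from_2x2(10, 100, 20, 100, "RR")  # RR 0.5
#' @export
ratio_from_2x2 <- function(events_a, total_a, events_b, total_b,
                           measure = c("OR", "RR"), level = 0.95) {
  measure <- match.arg(toupper(measure), c("OR", "RR"))
  for (v in c(events_a, total_a, events_b, total_b)) check_counts(0, max(1, v))
  if (total_a < 1 || total_b < 1) stop("arm totals must be at least 1")
  if (events_a > total_a || events_b > total_b) stop("events cannot exceed totals")
  a <- events_a; b <- total_a - events_a
  c_ <- events_b; d <- total_b - events_b
  if (measure == "OR") {
    if (min(a, b, c_, d) == 0) {
      stop("zero cell in 2x2 table: odds ratio standard error undefined")
    }
    point <- (a * d) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  } else {
    if (a == 0 || c_ == 0) {
      stop("zero event count: risk ratio standard error undefined")
    }
    point <- (a / total_a) / (c_ / total_b)
    se <- sqrt(1 / a - 1 / total_a + 1 / c_ - 1 / total_b)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- effect_estimate(point, exp(log(point) - z * se), exp(log(point) + z * se),
                         measure, level)
  attr(out, "se") <- se
  out
}
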