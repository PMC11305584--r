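# normalise a single pair to a plain list (accepts a one-row pair_table,
# a list, or a pair_table plus id via pairs[i, ])
as_pair_row <- function(pair) {
  if (is.data.frame(pair)) {
    if (nrow(pair) != 1L) stop("expected a single study pair (one row)")
    pair <- as.list(pair)
  }
  if (!is.list(pair) || is.null(pair$measure)) stop("not a study pair")
  pair
}

pair_side <- function(pair, side) {
  pre <- if (side == "original") "orig" else "rep"
  effect_estimate(pair[[paste0(pre, "_point")]], pair[[paste0(pre, "_lo")]],
                  pair[[paste0(pre, "_hi")]], pair$measure)
}

#' Do two confidence intervals overlap?
#'
#' Closed-interval semantics: a shared endpoint counts as overlap, so two
#' intervals overlap iff max(lo) <= min(hi). The criterion is symmetric and
#' reflexive, and widening either interval can only create overlap, never
#' remove it.
#'
#' @param a,b intervals: numeric \code{c(lo, hi)} or \code{effect_estimate}s.
#' @return logical.
#' @examples
#' intervals_overlap(c(0.26, 0.59), c(0.59, 0.74))  # TRUE, shared endpoint
#' @export
intervals_overlap <- function(a, b) {
  a <- interval_bounds(a); b <- interval_bounds(b)
  max(a[1], b[1]) <= min(a[2], b[2])
}

#' Is a point estimate inside an interval?
#'
#' Closed-interval semantics (boundary inclusive).
#'
#' @param point a numeric effect value.
#' @param iv an interval: numeric \code{c(lo, hi)} or an \code{effect_estimate}.
#' @return logical.
#' @export
point_in_interval <- function(point, iv) {
  iv <- interval_bounds(iv)
  iv[1] <= point && point <= iv[2]
}

#' Significance-direction concordance of a study pair
#'
#' The replication concords with a statistically significant original when
#' its own two-sided p-value (reconstructed from its printed CI on the log
#' scale) is below \code{alpha} and its effect lies on the same side of the
#' null (sign of the log point estimate) as the original's. Pairs whose
#' original carried no significance test (uncontrolled phase 1 trials) are
#' \code{"not_applicable"}; so are initially non-significant originals
#' unless \code{include_negatives = TRUE}, in which case a non-significant
#' original concords only with a non-significant replication (p >= alpha)
#' and is contradicted by a significant one.
#'
#' @param pair a single study pair (one row of a \code{\link{pair_table}}).
#' @param alpha significance threshold, default 0.05 two-sided.
#' @param include_negatives score initially non-significant originals too
#'   (sensitivity analysis)?
#' @return \code{"pass"}, \code{"fail"} or \code{"not_applicable"}.
#' @export
sig_concordant <- function(pair, alpha = 0.05, include_negatives = FALSE) {
  pair <- as_pair_row(pair)
  if (!is_ratio_measure(pair$measure)) {
    if (pair$original_significant != "not_applicable") {
      stop(sprintf("pair '%s': ORR pairs carry no significance test; annotation is inconsistent",
                   pair$pair_id))
    }
    return("not_applicable")
  }
  if (pair$original_significant == "not_applicable") return("not_applicable")
  if (pair$original_significant == "nonsignificant" && !include_negatives) {
    return("not_applicable")
  }
  rep_summary <- p_from_estimate(pair_side(pair, "replication"))
  rep_sig <- rep_summary$p < alpha
  if (pair$original_significant == "nonsignificant") {
    return(if (rep_sig) "fail" else "pass")
  }
  same_direction <- sign(rep_summary$log_point) ==
    sign(log(pair_side(pair, "original")$point))
  if (rep_sig && same_direction) "pass" else "fail"
}

#' Replication verdict for one study pair
#'
#' Evaluates every replication criterion for a pair: CI overlap (closed
#' intervals), forward containment (replication point inside the original's
#' CI), reverse containment (original point inside the replication's CI),
#' significance-direction concordance, and the aggregate primary criterion:
#' CI overlap AND concordance not failed. Pairs with no applicable
#' significance test are judged by overlap alone, so a
#' \code{"not_applicable"} concordance never fails the aggregate.
#'
#' @inheritParams sig_concordant
#' @return a one-row data.frame with columns \code{pair_id},
#'   \code{sig_concordant}, \code{ci_overlap}, \code{forward_containment},
#'   \code{reverse_containment}, \code{aggregate}.
#' @export
assess_pair <- function(pair, alpha = 0.05) {
  pair <- as_pair_row(pair)
  orig <- pair_side(pair, "original")
  repl <- pair_side(pair, "replication")
  overlap <- intervals_overlap(orig, repl)
  sig <- sig_concordant(pair, alpha = alpha, include_negatives = FALSE)
  data.frame(pair_id = pair$pair_id,
             sig_concordant = sig,
             ci_overlap = overlap,
             forward_containment = point_in_interval(repl$point, orig),
             reverse_containment = point_in_interval(orig$point, repl),
             aggregate = overlap && sig != "fail",
             stringsAsFactors = FALSE)
}

#' Replication verdicts for a whole pair table
#'
#' @param pairs a \code{\link{pair_table}}.
#' @param alpha significance threshold.
#' @return a data.frame of class \code{"replication_verdicts"}, one row per
#'   pair, as in \code{\link{assess_pair}}.
#' @export
assess_pairs <- function(pairs, alpha = 0.05) {
  stopifnot(inherits(pairs, "pair_table"))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    assess_pair(pairs[i, ], alpha = alpha)
  }))
  if (is.null(out)) {
    out <- data.frame(pair_id = character(), sig_concordant = character(),
                      ci_overlap = logical(), forward_containment = logical(),
                      reverse_containment = logical(), aggregate = logical(),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("replication_verdicts", "data.frame")
  out
}

CRITERIA <- c("significance", "overlap", "aggregate",
              "significance_with_negatives", "forward_containment",
              "reverse_containment")

#' Replication rates by criterion, with binomial confidence intervals
#'
#' Aggregates per-pair verdicts into one success rate per criterion, each
#' with its denominator: the significance criterion counts only pairs whose
#' original was statistically significant; the sensitivity variant adds the
#' initially non-significant originals (scored via
#' \code{\link{sig_concordant}} with \code{include_negatives = TRUE}); the
#' overlap, aggregate and containment criteria run over all pairs. Rate CIs
#' use the Wilson score interval by default (Wald available); the estimator
#' used is recorded in the \code{"estimator"} attribute. An empty
#' denominator yields an NA rate flagged undefined rather than an error.
#'
#' @param verdicts output of \code{\link{assess_pairs}}.
#' @param pairs the \code{\link{pair_table}} the verdicts came from.
#' @param alpha significance threshold for the sensitivity re-scoring.
#' @param interval \code{"wilson"} or \code{"wald"}.
#' @return a data.frame of class \code{"criterion_rates"} with columns
#'   \code{criterion}, \code{numerator}, \code{denominator}, \code{rate},
#'   \code{ci_lo}, \code{ci_hi}.
#' @export
criterion_rates <- function(verdicts, pairs, alpha = 0.05,
                            interval = c("wilson", "wald")) {
  interval <- match.arg(interval)
  stopifnot(nrow(verdicts) == nrow(pairs),
            all(verdicts$pair_id == pairs$pair_id))
  est_fun <- if (interval == "wilson") wilson_interval else wald_interval

  sig_applicable <- verdicts$sig_concordant != "not_applicable"
  with_neg <- vapply(seq_len(nrow(pairs)), function(i) {
    sig_concordant(pairs[i, ], alpha = alpha, include_negatives = TRUE)
  }, character(1))

  tally <- list(
    significance = c(sum(verdicts$sig_concordant == "pass"), sum(sig_applicable)),
    overlap = c(sum(verdicts$ci_overlap), nrow(verdicts)),
    aggregate = c(sum(verdicts$aggregate), nrow(verdicts)),
    significance_with_negatives = c(sum(with_neg == "pass"),
                                    sum(with_neg != "not_applicable")),
    forward_containment = c(sum(verdicts$forward_containment), nrow(verdicts)),
    reverse_containment = c(sum(verdicts$reverse_containment), nrow(verdicts))
  )
  rows <- lapply(CRITERIA, function(cr) {
    k <- tally[[cr]][1]; n <- tally[[cr]][2]
    if (n == 0) {
      data.frame(criterion = cr, numerator = 0L, denominator = 0L,
                 rate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      ci <- est_fun(k, n)
      data.frame(criterion = cr, numerator = as.integer(k), denominator = as.integer(n),
                 rate = k / n, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "estimator") <- interval
  class(out) <- c("criterion_rates", "data.frame")
  out
}

#' @export
print.criterion_rates <- function(x, ...) {
  cat(sprintf("Replication rates (%s intervals):\n", attr(x, "estimator")))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$rate[i])) {
      cat(sprintf("  %-28s undefined (n = 0)\n", x$criterion[i]))
    } else {
      cat(sprintf("  %-28s %d/%d = %.0f%% [%.0f, %.0f]\n", x$criterion[i],
                  x$numerator[i], x$denominator[i], 100 * x$rate[i],
                  100 * x$ci_lo[i], 100 * x$ci_hi[i]))
    }
  }
  invisible(x)
}
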