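#' Effect-size inflation ratio for one study pair
#'
#' The inflation ratio is oriented so that values above 1 mean the earlier
#' study showed the stronger effect. For unfavorable outcomes (death,
#' progression: effectiveness grows as the measure shrinks) it is
#' replication / original; for favorable outcomes (response, improvement)
#' it is original / replication. When \code{apply_inversion} is set and the
#' pair carries the publication-order flag (most of the replication
#' evidence predates the highly cited study), the ratio is inverted:
#' the highly cited study is then treated as the replication.
#'
#' @param pair a single study pair (one row of a \code{\link{pair_table}}).
#' @param apply_inversion honour the pair's \code{order_inverted} flag?
#' @return a one-row data.frame with \code{pair_id}, \code{ratio},
#'   \code{log_ratio}, \code{inverted}, \code{coined}.
#' @examples
#' pairs <- highly_cited_pairs()
#' pair_ratio(pairs[pairs$pair_id == "SHARP", ])  # ratio 1
#' @export
pair_ratio <- function(pair, apply_inversion = TRUE) {
  pair <- as_pair_row(pair)
  if (pair$orig_point <= 0 || pair$rep_point <= 0) {
    stop(sprintf("pair '%s': inflation ratio undefined for a zero point estimate",
                 pair$pair_id))
  }
  r <- if (pair$direction == "unfavorable") {
    pair$rep_point / pair$orig_point
  } else {
    pair$orig_point / pair$rep_point
  }
  inverted <- isTRUE(apply_inversion) && isTRUE(pair$order_inverted)
  if (inverted) r <- 1 / r
  data.frame(pair_id = pair$pair_id, ratio = r, log_ratio = log(r),
             inverted = inverted, coined = isTRUE(pair$coined),
             stringsAsFactors = FALSE)
}

#' Coin an effect estimate to the unfavorable orientation
#'
#' Converts a favorable-outcome effect into its unfavorable complement so
#' that all inflation ratios share one orientation: ORR becomes the
#' non-response rate 1 - ORR (interval [1 - hi, 1 - lo]); an odds ratio is
#' inverted to 1/OR (interval [1/hi, 1/lo]); a relative risk requires the
#' per-arm 2x2 counts, from which the complementary-outcome RR is computed
#' via \code{\link{ratio_from_2x2}} on the non-event counts. Coining an OR
#' leaves a pair's inflation ratio unchanged (1/rep over 1/orig equals
#' orig/rep); coining an ORR generally changes it.
#'
#' @param estimate an \code{\link{effect_estimate}} (ORR, OR, or RR).
#' @param counts for RR only: a list or vector with \code{events_a},
#'   \code{total_a}, \code{events_b}, \code{total_b}.
#' @return the coined \code{\link{effect_estimate}}.
#' @examples
#' coin_estimate(effect_estimate(0.38, 0.25, 0.44, "ORR"))  # 0.62 [0.56, 0.75]
#' @export
coin_estimate <- function(estimate, counts = NULL) {
  stopifnot(inherits(estimate, "effect_estimate"))
  switch(estimate$measure,
    ORR = effect_estimate(1 - estimate$point, 1 - estimate$hi, 1 - estimate$lo,
                          "ORR", estimate$level),
    OR = effect_estimate(1 / estimate$point, 1 / estimate$hi, 1 / estimate$lo,
                         "OR", estimate$level),
    RR = {
      if (is.null(counts)) {
        stop("coining a relative risk requires per-arm counts (complementary-outcome RR)")
      }
      counts <- as.list(counts)
      ratio_from_2x2(counts$total_a - counts$events_a, counts$total_a,
                     counts$total_b - counts$events_b, counts$total_b,
                     "RR", estimate$level)
    },
    stop("coining is defined for ORR, OR and RR measures only")
  )
}

#' Inflation ratios for a pair table
#'
#' Computes one inflation record per pair. With \code{coin = TRUE},
#' favorable-outcome pairs are first coined to the unfavorable orientation
#' (\code{\link{coin_estimate}} on both sides) and every ratio is then
#' replication / original; favorable relative-risk pairs lacking per-arm
#' counts cannot be coined and are excluded with a warning naming them.
#'
#' @param pairs a \code{\link{pair_table}}.
#' @param apply_inversion honour publication-order inversion flags?
#' @param coin convert favorable outcomes to unfavorable before the ratio?
#' @return a data.frame with one row per (retained) pair: \code{pair_id},
#'   \code{ratio}, \code{log_ratio}, \code{inverted}, \code{coined},
#'   \code{design}.
#' @export
inflation_records <- function(pairs, apply_inversion = TRUE, coin = FALSE) {
  stopifnot(inherits(pairs, "pair_table"))
  rows <- list(); dropped <- character()
  for (i in seq_len(nrow(pairs))) {
    pair <- as_pair_row(pairs[i, ])
    coined_here <- FALSE
    if (coin && pair$direction == "favorable") {
      if (pair$measure == "RR") {
        dropped <- c(dropped, pair$pair_id)
        next
      }
      orig <- coin_estimate(pair_side(pair, "original"))
      repl <- coin_estimate(pair_side(pair, "replication"))
      pair$orig_point <- orig$point; pair$orig_lo <- orig$lo; pair$orig_hi <- orig$hi
      pair$rep_point <- repl$point; pair$rep_lo <- repl$lo; pair$rep_hi <- repl$hi
      pair$direction <- "unfavorable"
      coined_here <- TRUE
    }
    rec <- pair_ratio(pair, apply_inversion = apply_inversion)
    rec$coined <- coined_here
    rec$design <- pair$original_design
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(dropped)) {
    warning("excluded from coined analysis (favorable RR without per-arm counts): ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pair_id = character(), ratio = numeric(),
                      log_ratio = numeric(), inverted = logical(),
                      coined = logical(), design = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarise inflation ratios on the log scale
#'
#' The summary statistic is the geometric mean of the inflation ratios:
#' natural logs are averaged, a t-based 95% CI and a two-sided one-sample
#' t-test against a mean log ratio of 0 (no systematic inflation) are
#' computed, and mean and CI are exponentiated back to the ratio scale.
#' With a single record only the mean is defined; with zero variance the
#' test is degenerate and p = 1 is returned with a warning.
#'
#' @param records output of \code{\link{inflation_records}} (or any
#'   data.frame with a \code{log_ratio} column; a \code{design} column is
#'   needed for subgroup filters).
#' @param subgroup \code{"all"}, \code{"phase1"} or \code{"RCT"}.
#' @param level confidence level for the t interval.
#' @return an object of class \code{"inflation_summary"}: list with
#'   \code{mean_ratio}, \code{ci}, \code{p}, \code{n}, \code{subgroup}.
#' @export
summarize_inflation <- function(records, subgroup = c("all", "phase1", "RCT"),
                                level = 0.95) {
  subgroup <- match.arg(subgroup)
  if (subgroup != "all") {
    if (is.null(records$design)) stop("records lack a 'design' column for subgroup filtering")
    records <- records[records$design == subgroup, , drop = FALSE]
  }
  n <- nrow(records)
  if (n == 0) stop("undefined inflation summary: no records", if (subgroup != "all") paste0(" in subgroup '", subgroup, "'") else "")
  lr <- records$log_ratio
  m <- mean(lr)
  if (n == 1) {
    out <- list(mean_ratio = exp(m), ci = c(lo = NA_real_, hi = NA_real_),
                p = NA_real_, n = n, subgroup = subgroup)
  } else if (stats::sd(lr) == 0) {
    warning("zero variance in log inflation ratios; t-test degenerate, p set to 1")
    out <- list(mean_ratio = exp(m), ci = c(lo = exp(m), hi = exp(m)),
                p = 1, n = n, subgroup = subgroup)
  } else {
    tt <- stats::t.test(lr, mu = 0, conf.level = level)
    out <- list(mean_ratio = exp(m),
                ci = c(lo = exp(tt$conf.int[1]), hi = exp(tt$conf.int[2])),
                p = tt$p.value, n = n, subgroup = subgroup)
  }
  class(out) <- "inflation_summary"
  out
}

#' @export
print.inflation_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Mean inflation ratio (%s, n = %d): %s [%s, %s], t-test p = %s\n",
              x$subgroup, x$n, format(x$mean_ratio, digits = digits),
              format(x$ci[["lo"]], digits = digits), format(x$ci[["hi"]], digits = digits),
              format(x$p, digits = digits)))
  invisible(x)
}

INFLATION_ANALYSES <- c("main", "publication_order", "coining",
                        "publication_order_coining")

#' The four inflation analyses, by subgroup
#'
#' Runs the main analysis (publication-order inversion applied, no coining)
#' and its three sensitivity variants: "publication_order" (no inversion:
#' the highly cited study is always the reference), "coining" (favorable
#' outcomes converted to unfavorable; inversion applied) and
#' "publication_order_coining" (both). Each analysis is summarised over all
#' pairs and over the phase-1 and RCT subgroups.
#'
#' @param pairs a \code{\link{pair_table}}.
#' @return a data.frame of class \code{"inflation_table"}: one row per
#'   (analysis, subgroup) with \code{mean_ratio}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{n}.
#' @export
inflation_analyses <- function(pairs) {
  settings <- list(main = c(inv = TRUE, coin = FALSE),
                   publication_order = c(inv = FALSE, coin = FALSE),
                   coining = c(inv = TRUE, coin = TRUE),
                   publication_order_coining = c(inv = FALSE, coin = TRUE))
  rows <- list()
  for (an in names(settings)) {
    recs <- suppressWarnings(inflation_records(pairs,
                                               apply_inversion = settings[[an]][["inv"]],
                                               coin = settings[[an]][["coin"]]))
    for (sg in c("all", "phase1", "RCT")) {
      has <- if (sg == "all") nrow(recs) > 0 else any(recs$design == sg)
      if (!has) next
      s <- summarize_inflation(recs, subgroup = sg)
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = an, subgroup = sg, mean_ratio = s$mean_ratio,
        ci_lo = s$ci[["lo"]], ci_hi = s$ci[["hi"]], p = s$p, n = s$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("inflation_table", "data.frame")
  out
}

#' @export
print.inflation_table <- function(x, ...) {
  cat("Effect-size inflation (geometric mean ratio [95% CI], t-test p):\n")
  for (an in unique(x$analysis)) {
    sub <- x[x$analysis == an, ]
    all_row <- sub[sub$subgroup == "all", ]
    cat(sprintf("  %-26s %.2f [%.2f, %.2f]  p = %.2f  (n = %d)\n", an,
                all_row$mean_ratio, all_row$ci_lo, all_row$ci_hi, all_row$p,
                all_row$n))
  }
  invisible(x)
}
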