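#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p by summation of the hypergeometric probabilities (fixed margins)
#' of all tables no more probable than the observed one -- the dominant
#' two-sided convention. A zero row or column margin makes the table
#' uninformative: p = 1 is returned with a warning.
#'
#' @param table a 2x2 matrix of nonnegative integer counts.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 2, 16, 1), 2, byrow = TRUE))  # ~0.19
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin in 2x2 table; test is uninformative, p = 1")
    return(1)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by enumeration when the combined sample size is at most 10 and
#' there are no ties; otherwise the normal approximation with the tie
#' correction (no continuity correction, so identical samples give p = 1).
#'
#' @param x,y nonempty numeric samples.
#' @return the two-sided p-value, with the U statistic of the first sample
#'   attached as attribute \code{"U"}.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 10 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = FALSE))
  p <- min(1, wt$p.value)
  attr(p, "U") <- unname(wt$statistic)
  p
}

num_summary <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("median %g [IQR %g-%g]", q[2], q[1], q[3])
}

cat_summary <- function(values, success) {
  lv <- sort(unique(values))
  paste(vapply(lv, function(l) {
    sprintf("%s: %d/%d", l, sum(success & values == l), sum(values == l))
  }, character(1)), collapse = "; ")
}

#' Compare predictors between replicated and contradicted pairs
#'
#' For a chosen replication criterion, splits pairs into replicated
#' (criterion passed) and contradicted (failed) and compares candidate
#' predictors between the groups: study design (phase 1 vs RCT; skipped
#' for the significance criterion, under which phase 1 trials are not
#' scored) and intervention type by Fisher's exact test; citations per
#' year, original sample size and original p-value by the Mann-Whitney U
#' test, with medians and IQRs reported per group. Pairs missing a
#' predictor value are excluded from that comparison only; a comparison
#' with an empty group, or with no non-missing values, is flagged
#' undefined (NA p-value).
#'
#' @param pairs a \code{\link{pair_table}}.
#' @param verdicts matching \code{\link{assess_pairs}} output.
#' @param criterion \code{"overlap"}, \code{"aggregate"} or
#'   \code{"significance"}.
#' @return a data.frame of class \code{"predictor_comparisons"}: one row
#'   per predictor with the test used, group summaries and p-value.
#' @export
compare_predictors <- function(pairs, verdicts,
                               criterion = c("overlap", "aggregate", "significance")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(pairs) == nrow(verdicts), all(pairs$pair_id == verdicts$pair_id))
  if (criterion == "significance") {
    keep <- verdicts$sig_concordant != "not_applicable"
    success <- verdicts$sig_concordant[keep] == "pass"
  } else {
    keep <- rep(TRUE, nrow(pairs))
    success <- if (criterion == "overlap") verdicts$ci_overlap else verdicts$aggregate
  }
  sub <- pairs[keep, , drop = FALSE]

  predictors <- list(
    original_design = "categorical",
    intervention_type = "categorical",
    citations_per_year = "continuous",
    original_n = "continuous",
    original_p = "continuous"
  )
  if (criterion == "significance") predictors$original_design <- NULL

  rows <- list()
  for (pred in names(predictors)) {
    kind <- predictors[[pred]]
    vals <- sub[[pred]]
    ok <- !is.na(vals)
    v <- vals[ok]; s <- success[ok]
    row <- data.frame(predictor = pred, criterion = criterion,
                      test = if (kind == "categorical") "fisher_exact" else "mann_whitney",
                      replicated_summary = NA_character_,
                      contradicted_summary = NA_character_,
                      p = NA_real_, n_used = length(v), stringsAsFactors = FALSE)
    if (length(v) && any(s) && any(!s)) {
      if (kind == "categorical") {
        lv <- sort(unique(v))
        row$replicated_summary <- cat_summary(v, s)
        row$contradicted_summary <- cat_summary(v, !s)
        if (length(lv) == 2) {
          tab <- rbind(c(sum(s & v == lv[1]), sum(!s & v == lv[1])),
                       c(sum(s & v == lv[2]), sum(!s & v == lv[2])))
          row$p <- suppressWarnings(fisher_exact_2x2(tab))
        }
      } else {
        row$replicated_summary <- num_summary(v[s])
        row$contradicted_summary <- num_summary(v[!s])
        row$p <- as.numeric(mann_whitney_u(v[s], v[!s]))
      }
    }
    rows[[pred]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("predictor_comparisons", "data.frame")
  out
}

#' @export
print.predictor_comparisons <- function(x, ...) {
  cat(sprintf("Predictor comparisons (criterion: %s):\n", x$criterion[1]))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$p[i])) {
      cat(sprintf("  %-20s undefined (missing values or empty group)\n", x$predictor[i]))
    } else {
      cat(sprintf("  %-20s %s | replicated %s | contradicted %s | p = %.2f\n",
                  x$predictor[i], x$test[i], x$replicated_summary[i],
                  x$contradicted_summary[i], x$p[i]))
    }
  }
  invisible(x)
}
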