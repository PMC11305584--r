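#' Full replication assessment of a pair table
#'
#' The package's main entry point. Given a table of (original, replication)
#' effect-estimate pairs it computes per-pair replication verdicts under
#' every criterion, criterion-level success rates with binomial CIs, the
#' four effect-size inflation analyses with phase-1/RCT subgroups, and
#' predictor comparisons between replicated and contradicted pairs. All
#' computation is deterministic given the inputs and options; display
#' rounding (whole percents for rates, two decimals for ratios) happens
#' only in the print methods, never in the stored values.
#'
#' @param pairs a \code{\link{pair_table}}.
#' @param alpha two-sided significance threshold, default 0.05.
#' @param interval binomial interval estimator for rate CIs:
#'   \code{"wilson"} (default) or \code{"wald"}.
#' @param apply_inversion honour publication-order inversion flags in the
#'   main inflation analysis?
#' @param source_tag free-text provenance label stored in the report
#'   (e.g. an input path or \code{"bundled"}).
#' @return an object of class \code{"replication_analysis"}: a list with
#'   elements \code{pairs}, \code{verdicts}, \code{rates},
#'   \code{inflation}, \code{inflation_pairs}, \code{predictors} and
#'   \code{options}.
#' @examples
#' fit <- replication_analysis(highly_cited_pairs())
#' fit
#' @export
replication_analysis <- function(pairs, alpha = 0.05,
                                 interval = c("wilson", "wald"),
                                 apply_inversion = TRUE,
                                 source_tag = "user") {
  stopifnot(inherits(pairs, "pair_table"))
  interval <- match.arg(interval)
  if (nrow(pairs) == 0) {
    warning("empty pair table: rates and summaries are undefined")
  }
  verdicts <- assess_pairs(pairs, alpha = alpha)
  rates <- if (nrow(pairs)) criterion_rates(verdicts, pairs, alpha = alpha,
                                            interval = interval) else NULL
  inflation <- if (nrow(pairs)) inflation_analyses(pairs) else NULL
  inflation_pairs <- if (nrow(pairs)) {
    inflation_records(pairs, apply_inversion = apply_inversion)
  } else NULL
  predictors <- if (nrow(pairs)) {
    crits <- c("overlap", "aggregate", "significance")
    do.call(rbind, lapply(crits, function(cr) {
      as.data.frame(compare_predictors(pairs, verdicts, criterion = cr))
    }))
  } else NULL

  structure(list(
    pairs = pairs, verdicts = verdicts, rates = rates,
    inflation = inflation, inflation_pairs = inflation_pairs,
    predictors = predictors,
    options = list(alpha = alpha, interval = interval,
                   apply_inversion = apply_inversion,
                   boundary_rule = "closed",
                   source = source_tag,
                   package_version = as.character(utils::packageVersion("replicheck")))),
    class = "replication_analysis")
}

#' @export
print.replication_analysis <- function(x, ...) {
  cat(sprintf("Replication assessment of %d study pair%s (alpha = %g, %s intervals)\n\n",
              nrow(x$pairs), if (nrow(x$pairs) == 1) "" else "s",
              x$options$alpha, x$options$interval))
  if (is.null(x$rates)) {
    cat("  no pairs: rates undefined (n = 0)\n")
    return(invisible(x))
  }
  print(x$rates)
  cat("\n")
  print(x$inflation)
  invisible(x)
}

#' @export
summary.replication_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-pair verdicts:\n")
  print(as.data.frame(object$verdicts), row.names = FALSE)
  if (!is.null(object$predictors)) {
    cat("\nPredictor comparisons:\n")
    show <- object$predictors[, c("predictor", "criterion", "test", "p")]
    print(show, row.names = FALSE)
  }
  invisible(object)
}

#' Write an analysis report to JSON
#'
#' Serialises criterion rates, per-pair verdicts, inflation rows and
#' records, predictor comparisons and the provenance options block to a
#' JSON document. \code{\link{read_report_json}} restores the content at
#' full printed precision (15 significant digits). Rates for an empty
#' analysis are written as an explicit \code{"undefined (n=0)"} flag.
#'
#' @param report a \code{\link{replication_analysis}} object.
#' @param path output file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "replication_analysis"))
  payload <- list(
    options = report$options,
    rates = if (is.null(report$rates)) "undefined (n=0)" else as.data.frame(report$rates),
    verdicts = as.data.frame(report$verdicts),
    inflation = if (is.null(report$inflation)) "undefined (n=0)" else as.data.frame(report$inflation),
    inflation_pairs = if (is.null(report$inflation_pairs)) NULL else as.data.frame(report$inflation_pairs),
    predictors = if (is.null(report$predictors)) NULL else as.data.frame(report$predictors)
  )
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write report: directory does not exist: ", dir)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis report back from JSON
#'
#' @param path a file written by \code{\link{write_report_json}}.
#' @return a list with the report's data.frames and options.
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
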