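PAIR_COLUMNS <- c("pair_id", "measure", "orig_point", "orig_lo", "orig_hi",
                  "rep_point", "rep_lo", "rep_hi", "direction",
                  "original_significant", "order_inverted", "original_design",
                  "intervention_type", "citations_per_year", "original_n",
                  "original_p")

PAIR_NUMERIC <- c("orig_point", "orig_lo", "orig_hi", "rep_point", "rep_lo",
                  "rep_hi", "citations_per_year", "original_n", "original_p")

#' Construct and validate a table of study pairs
#'
#' A pair table holds one row per (original study, replication) pair of effect
#' estimates sharing the same effect measure, with the annotations the
#' replication criteria and inflation analyses need: outcome direction
#' (whether effectiveness increases or decreases with the outcome measure),
#' significance status of the original, a publication-order inversion flag,
#' the original's design and intervention type, and optional predictor
#' columns (citations per year, sample size, original p-value).
#'
#' Validation enforces, per pair: interval bounds containing the point on
#' both sides, positivity for ratio measures, [0, 1] bounds for ORR,
#' unique pair ids, and the design rule that uncontrolled phase 1 originals
#' carry \code{original_significant == "not_applicable"}.
#'
#' @param df a data.frame with the columns listed in \code{\link{read_pairs_csv}}.
#' @return the validated data.frame with class \code{"pair_table"}.
#' @seealso \code{\link{read_pairs_csv}}, \code{\link{highly_cited_pairs}}
#' @export
pair_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(PAIR_COLUMNS, c("citations_per_year", "original_n", "original_p")),
                          names(df))
  if (length(missing_cols)) {
    stop("pair table is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("citations_per_year", "original_n", "original_p")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  df <- df[, PAIR_COLUMNS]
  df$measure <- toupper(df$measure)
  df$order_inverted <- as.logical(df$order_inverted)
  if (anyNA(df$order_inverted)) stop("order_inverted must be TRUE/FALSE")
  if (anyDuplicated(df$pair_id)) {
    stop("duplicated pair_id: ", paste(unique(df$pair_id[duplicated(df$pair_id)]), collapse = ", "))
  }
  check_levels <- function(col, levels) {
    bad <- !df[[col]] %in% levels
    if (any(bad)) {
      stop(sprintf("invalid %s for pair '%s' (must be one of: %s)",
                   col, df$pair_id[which(bad)[1]], paste(levels, collapse = ", ")))
    }
  }
  check_levels("measure", EFFECT_MEASURES)
  check_levels("direction", c("favorable", "unfavorable"))
  check_levels("original_significant", c("significant", "nonsignificant", "not_applicable"))
  check_levels("original_design", c("RCT", "phase1", "cohort"))
  ok_type <- df$intervention_type %in% c("pharmacological", "nonpharmacological") |
    is.na(df$intervention_type)
  if (!all(ok_type)) {
    stop("invalid intervention_type for pair '", df$pair_id[which(!ok_type)[1]], "'")
  }
  bad_phase1 <- df$original_design == "phase1" & df$original_significant != "not_applicable"
  if (any(bad_phase1)) {
    stop("pair '", df$pair_id[which(bad_phase1)[1]],
         "': phase 1 originals have no significance test; use original_significant = 'not_applicable'")
  }
  for (i in seq_len(nrow(df))) {
    for (side in c("original", "replication")) {
      est <- try(pair_estimate(df, i, side), silent = TRUE)
      if (inherits(est, "try-error")) {
        stop(sprintf("invalid %s estimate for pair '%s': %s", side, df$pair_id[i],
                     conditionMessage(attr(est, "condition"))))
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("pair_table", "data.frame")
  df
}

#' Extract one side of a study pair as an effect estimate
#'
#' @param pairs a \code{pair_table}.
#' @param which row index or pair_id.
#' @param side \code{"original"} or \code{"replication"}.
#' @return an \code{\link{effect_estimate}}.
#' @export
pair_estimate <- function(pairs, which, side = c("original", "replication")) {
  side <- match.arg(side)
  i <- if (is.character(which)) match(which, pairs$pair_id) else which
  if (is.na(i) || i < 1 || i > nrow(pairs)) stop("pair not found: ", which)
  pre <- if (side == "original") "orig" else "rep"
  effect_estimate(pairs[[paste0(pre, "_point")]][i], pairs[[paste0(pre, "_lo")]][i],
                  pairs[[paste0(pre, "_hi")]][i], pairs$measure[i])
}

#' Read a pair table from CSV
#'
#' The file must be comma-delimited UTF-8 with a header naming exactly the
#' documented columns: \code{pair_id, measure, orig_point, orig_lo, orig_hi,
#' rep_point, rep_lo, rep_hi, direction, original_significant,
#' order_inverted, original_design, intervention_type, citations_per_year,
#' original_n, original_p}. The last three are optional and may be empty.
#' Malformed numeric cells raise an error naming the row and column;
#' violated estimate invariants raise an error naming the pair.
#'
#' @param path path to a CSV file.
#' @return a \code{\link{pair_table}}.
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  required <- setdiff(PAIR_COLUMNS, c("citations_per_year", "original_n", "original_p"))
  if (!all(required %in% names(raw))) {
    stop("CSV header does not match the pair-table schema; missing: ",
         paste(setdiff(required, names(raw)), collapse = ", "))
  }
  for (col in intersect(PAIR_NUMERIC, names(raw))) {
    cell <- trimws(raw[[col]])
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop(sprintf("malformed numeric value '%s' in column '%s', data row %d",
                   cell[bad[1]], col, bad[1]))
    }
    raw[[col]] <- num
  }
  if (nrow(raw) > 0) {
    mandatory_num <- c("orig_point", "orig_lo", "orig_hi", "rep_point", "rep_lo", "rep_hi")
    for (col in mandatory_num) {
      if (anyNA(raw[[col]])) {
        stop(sprintf("missing value in required column '%s', data row %d",
                     col, which(is.na(raw[[col]]))[1]))
      }
    }
  }
  pair_table(raw)
}

#' Write a pair table to CSV
#'
#' Inverse of \code{\link{read_pairs_csv}}: writing then reading restores the
#' table on all fields.
#'
#' @param pairs a \code{pair_table}.
#' @param path output path.
#' @export
write_pairs_csv <- function(pairs, path) {
  stopifnot(inherits(pairs, "pair_table"))
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Bundled highly cited study pairs (2004-2018 clinical literature)
#'
#' Returns the packaged dataset of 24 pairs of highly cited clinical studies
#' and their replications, transcribed from the published effect sizes:
#' 7 uncontrolled phase 1 oncology trials measured by objective response rate
#' and 17 randomized controlled trials measured by OR, RR, HR or IRR.
#' Outcome direction is favorable for the 7 ORR pairs and the four stroke
#' disability pairs (EXTEND-IA, MR-CLEAN, ECASS-III, ESCAPE), unfavorable
#' otherwise; ACCORD and PARTNER-A are the two initially non-significant
#' originals; EURTAC, Cheng2009, ESCAPE and NEJSG carry the
#' publication-order inversion flag (most of the replication evidence
#' predates the highly cited study).
#'
#' @return a \code{\link{pair_table}} with 24 rows.
#' @examples
#' pairs <- highly_cited_pairs()
#' table(pairs$measure)
#' @export
highly_cited_pairs <- function() {
  path <- system.file("extdata", "highly_cited_pairs.csv", package = "replicheck",
                      mustWork = TRUE)
  read_pairs_csv(path)
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("Study pair table: %d pair%s\n", nrow(x), if (nrow(x) == 1) "" else "s"))
  if (nrow(x)) {
    shown <- data.frame(pair_id = x$pair_id, measure = x$measure,
                        original = sprintf("%g [%g, %g]", x$orig_point, x$orig_lo, x$orig_hi),
                        replication = sprintf("%g [%g, %g]", x$rep_point, x$rep_lo, x$rep_hi),
                        design = x$original_design, direction = x$direction)
    print(shown, row.names = FALSE)
  }
  invisible(x)
}
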