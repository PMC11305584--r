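META_COLUMNS <- c("study_id", "year", "n", "events_a", "total_a", "events_b",
                  "total_b", "log_effect", "se", "is_index")

#' Construct and validate a meta-analysis study table
#'
#' One row per study in a meta-analysis. Each study carries either per-arm
#' 2x2 counts (\code{events_a, total_a, events_b, total_b}) or a
#' log-transformed effect with its standard error (\code{log_effect, se});
#' at most one study is flagged as the index (highly cited) study.
#'
#' @param df a data.frame with (a subset of) the columns above.
#' @return the validated data.frame with class \code{"meta_table"}.
#' @export
meta_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) < 1) stop("a meta-analysis set needs at least one study")
  for (col in META_COLUMNS) if (!col %in% names(df)) df[[col]] <- NA
  df <- df[, META_COLUMNS]
  df$is_index <- as.logical(df$is_index)
  df$is_index[is.na(df$is_index)] <- FALSE
  if (sum(df$is_index) > 1) stop("at most one index study is allowed")
  if (anyDuplicated(df$study_id)) stop("duplicated study_id")
  has_counts <- !is.na(df$events_a) & !is.na(df$total_a) &
    !is.na(df$events_b) & !is.na(df$total_b)
  has_logeff <- !is.na(df$log_effect) & !is.na(df$se)
  if (any(!has_counts & !has_logeff)) {
    stop("study '", df$study_id[which(!has_counts & !has_logeff)[1]],
         "' carries neither 2x2 counts nor (log_effect, se)")
  }
  if (any(has_logeff & df$se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  attr(df, "has_counts") <- has_counts
  class(df) <- c("meta_table", "data.frame")
  df
}

#' Read a meta-analysis study table from CSV
#'
#' Same CSV dialect as the pair table: comma-delimited UTF-8 with header
#' \code{study_id, year, n, events_a, total_a, events_b, total_b,
#' log_effect, se, is_index}; empty cells are missing.
#'
#' @param path path to a CSV file.
#' @return a \code{\link{meta_table}}.
#' @export
read_meta_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  num_cols <- setdiff(META_COLUMNS, c("study_id", "is_index"))
  for (col in intersect(num_cols, names(raw))) {
    cell <- trimws(raw[[col]]); cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop(sprintf("malformed numeric value '%s' in column '%s', data row %d",
                   cell[bad[1]], col, bad[1]))
    }
    raw[[col]] <- num
  }
  if ("is_index" %in% names(raw)) raw$is_index <- toupper(trimws(raw$is_index)) %in% c("TRUE", "T", "1")
  meta_table(raw)
}

# per-study log effects and variances; 2x2 rows go through ratio_from_2x2
study_log_effects <- function(set, measure) {
  has_counts <- attr(set, "has_counts")
  yi <- vi <- numeric(nrow(set))
  for (i in seq_len(nrow(set))) {
    if (has_counts[i] && measure %in% c("OR", "RR")) {
      est <- ratio_from_2x2(set$events_a[i], set$total_a[i],
                            set$events_b[i], set$total_b[i], measure)
      yi[i] <- log(est$point)
      vi[i] <- attr(est, "se")^2
    } else if (!is.na(set$log_effect[i]) && !is.na(set$se[i])) {
      yi[i] <- set$log_effect[i]
      vi[i] <- set$se[i]^2
    } else {
      stop("study '", set$study_id[i], "' has no usable effect data for measure ", measure)
    }
  }
  list(yi = yi, vi = vi)
}

# Mantel-Haenszel common-effect estimate from 2x2 counts (no correction)
mh_common_effect <- function(set, measure) {
  a <- set$events_a; n1 <- set$total_a
  c_ <- set$events_b; n2 <- set$total_b
  N <- n1 + n2
  if (measure == "RR") {
    sum(a * n2 / N) / sum(c_ * n1 / N)
  } else {
    b <- n1 - a; d <- n2 - c_
    sum(a * d / N) / sum(b * c_ / N)
  }
}

#' Random-effects pooled estimate (DerSimonian-Laird)
#'
#' Pools a meta-analysis set on the log scale. Per-study effects come from
#' the 2x2 counts when available (via \code{\link{ratio_from_2x2}}) or from
#' the supplied (log_effect, se). Between-study variance is the
#' DerSimonian-Laird method-of-moments estimate, truncated at zero, and the
#' pooled effect is the inverse-variance weighted mean with weights
#' 1 / (vi + tau2). When every study carries counts, the Mantel-Haenszel
#' common-effect estimate is also computed and attached as the
#' \code{"mh_common"} attribute (it is the common-effect step of the
#' Mantel-Haenszel random-effects procedure and equals the pooled point
#' when tau2 = 0 only approximately). A single-study set returns that
#' study's effect unchanged, flagged with attribute \code{k = 1}.
#'
#' @param set a \code{\link{meta_table}}.
#' @param measure effect measure of the pooled estimate (\code{"OR"},
#'   \code{"RR"}, \code{"HR"}, \code{"IRR"}).
#' @param level confidence level of the pooled interval.
#' @return an \code{\link{effect_estimate}} with attributes \code{k},
#'   \code{tau2}, \code{Q}, and (when counts allow) \code{mh_common}.
#' @export
pool_random_effects <- function(set, measure = "RR", level = 0.95) {
  stopifnot(inherits(set, "meta_table"))
  measure <- match.arg(toupper(measure), RATIO_MEASURES)
  eff <- study_log_effects(set, measure)
  k <- length(eff$yi)
  if (k == 1) {
    out <- effect_estimate(exp(eff$yi), exp(eff$yi - stats::qnorm(1 - (1 - level) / 2) * sqrt(eff$vi)),
                           exp(eff$yi + stats::qnorm(1 - (1 - level) / 2) * sqrt(eff$vi)),
                           measure, level)
    attr(out, "k") <- 1L
    attr(out, "tau2") <- 0
    return(out)
  }
  wi <- 1 / eff$vi
  ybar <- sum(wi * eff$yi) / sum(wi)
  Q <- sum(wi * (eff$yi - ybar)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
  wstar <- 1 / (eff$vi + tau2)
  mu <- sum(wstar * eff$yi) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- effect_estimate(exp(mu), exp(mu - z * se), exp(mu + z * se), measure, level)
  attr(out, "k") <- as.integer(k)
  attr(out, "tau2") <- tau2
  attr(out, "Q") <- Q
  if (all(attr(set, "has_counts")) && measure %in% c("OR", "RR")) {
    attr(out, "mh_common") <- mh_common_effect(set, measure)
  }
  out
}

#' Leave-one-out re-estimation without the index study
#'
#' Re-pools a meta-analysis after removing the highly cited (index) study,
#' turning the meta-analytic estimate into a replication independent of it.
#' When exactly one study remains, that study's effect is returned verbatim
#' (the two-study rule: a meta-analysis of the index study plus one other
#' study is replaced by the other study itself, with no refitting).
#'
#' @inheritParams pool_random_effects
#' @return an \code{\link{effect_estimate}}.
#' @export
leave_one_out <- function(set, measure = "RR", level = 0.95) {
  stopifnot(inherits(set, "meta_table"))
  if (!any(set$is_index)) stop("set has no index study to remove")
  rest <- set[!set$is_index, , drop = FALSE]
  if (nrow(rest) == 0) stop("only the index study is present; nothing remains after removal")
  rest <- meta_table(rest)
  pool_random_effects(rest, measure = measure, level = level)
}

#' Sample-size contribution of the index study
#'
#' Fraction of the meta-analysis total sample size contributed by the index
#' (highly cited) study. Meta-analyses where this fraction is 0.5 or more
#' are not eligible replications.
#'
#' @param set a \code{\link{meta_table}} with all \code{n} known.
#' @return a proportion in [0, 1].
#' @export
contribution_fraction <- function(set) {
  stopifnot(inherits(set, "meta_table"))
  if (!any(set$is_index)) stop("set has no index study")
  if (anyNA(set$n)) stop("sample sizes must be known for all studies")
  sum(set$n[set$is_index]) / sum(set$n)
}

#' Does the evidence preceding the index study outweigh what followed it?
#'
#' TRUE when the pooled sample size of studies published strictly before
#' the index study's year exceeds (strictly) that of studies published
#' strictly after it. Drives the publication-order inversion flag for new
#' datasets: when most of the evidence predates the highly cited study, the
#' highly cited study is the de-facto replication. Same-year studies count
#' on neither side (year is the only ordering available), and ties resolve
#' to FALSE.
#'
#' @param set a \code{\link{meta_table}} with years and sample sizes known.
#' @return logical.
#' @export
preceding_mass_exceeds <- function(set) {
  stopifnot(inherits(set, "meta_table"))
  if (!any(set$is_index)) stop("set has no index study")
  if (anyNA(set$year)) stop("publication years must be known for all studies")
  if (anyNA(set$n)) stop("sample sizes must be known for all studies")
  y0 <- set$year[set$is_index][1]
  rest <- set[!set$is_index, , drop = FALSE]
  sum(rest$n[rest$year < y0]) > sum(rest$n[rest$year > y0])
}

DESIGN_TIERS <- c(uncontrolled = 1, cohort = 2, RCT = 3, meta_analysis = 4)

#' Select the best eligible replication for a study
#'
#' A candidate replication is eligible if it has a strictly higher strength
#' of evidence tier than the original (meta-analysis > RCT > cohort >
#' uncontrolled), or the same tier with a sample size equal to or larger
#' than the original's. Meta-analysis candidates must additionally have an
#' index-study contribution fraction below 0.5. Among the eligible, the one
#' with the largest sample size wins; exact ties break deterministically by
#' lexicographic \code{study_id}. With no eligible candidate the original
#' is unchallenged and \code{NULL} is returned (not an error).
#'
#' @param original a list with \code{tier} (one of \code{"uncontrolled"},
#'   \code{"cohort"}, \code{"RCT"}, \code{"meta_analysis"}) and \code{n}.
#' @param candidates a data.frame with columns \code{study_id}, \code{tier},
#'   \code{n} and optionally \code{contribution} (the index-study sample
#'   fraction, for meta-analysis candidates).
#' @return the chosen candidate as a one-row data.frame, or \code{NULL}
#'   when the study is unchallenged.
#' @export
select_replication <- function(original, candidates) {
  stopifnot(is.list(original), original$tier %in% names(DESIGN_TIERS),
            is.data.frame(candidates))
  if (!nrow(candidates)) return(NULL)
  if (!all(candidates$tier %in% names(DESIGN_TIERS))) stop("unknown candidate design tier")
  if (is.null(candidates$contribution)) candidates$contribution <- NA_real_
  tier0 <- DESIGN_TIERS[[original$tier]]
  tiers <- DESIGN_TIERS[candidates$tier]
  eligible <- tiers > tier0 | (tiers == tier0 & candidates$n >= original$n)
  is_meta <- candidates$tier == "meta_analysis"
  eligible <- eligible & (!is_meta | (!is.na(candidates$contribution) &
                                        candidates$contribution < 0.5))
  if (!any(eligible)) return(NULL)
  pool <- candidates[eligible, , drop = FALSE]
  pool <- pool[order(-pool$n, pool$study_id), , drop = FALSE]
  pool[1, , drop = FALSE]
}
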