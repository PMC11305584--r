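#' Configuration for the synthetic pair generator
#'
#' Defaults emulate the structure of the bundled highly cited pairs:
#' 24 pairs of which 7/24 are phase-1 ORR pairs; ratio-measure true log
#' effects drawn from N(mu = -0.45, tau = 0.35) (typical protective ratio
#' around 0.64); original log-scale standard errors lognormal with median
#' 0.14; replications better powered, with SEs half those of the originals;
#' phase-1 response rates uniform on [0.15, 0.45] with 30 original and 300
#' replication patients. The optional significance filter retains only
#' pairs whose original reaches two-sided p < alpha, redrawing rejected
#' pairs up to \code{retry_factor * n_pairs} attempts (winner's-curse
#' experiments).
#'
#' @param n_pairs number of pairs to generate.
#' @param prop_orr expected proportion of ORR (phase-1) pairs; the count is
#'   \code{round(prop_orr * n_pairs)}.
#' @param mu,tau mean and SD of the true log effect for ratio pairs.
#' @param se_meanlog,se_sdlog lognormal parameters of the original's
#'   log-scale standard error.
#' @param rep_se_factor replication SE as a multiple of the original's
#'   (typically < 1: replications are larger).
#' @param orr_p_range range of true response rates for ORR pairs.
#' @param orr_n_original,orr_n_replication patients per ORR trial.
#' @param select_original_significant keep only pairs with a significant
#'   original (ratio pairs only; ORR pairs carry no test).
#' @param alpha significance threshold for the filter.
#' @param direction direction label assigned to every pair
#'   (\code{"unfavorable"} by default; a semantic label independent of the
#'   effect's sign).
#' @param measure measure label for ratio pairs.
#' @param retry_factor retry budget multiplier for the significance filter.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_pairs = 24, prop_orr = 7 / 24, mu = -0.45, tau = 0.35,
                       se_meanlog = log(0.14), se_sdlog = 0.4,
                       rep_se_factor = 0.5, orr_p_range = c(0.15, 0.45),
                       orr_n_original = 30, orr_n_replication = 300,
                       select_original_significant = FALSE, alpha = 0.05,
                       direction = c("unfavorable", "favorable"),
                       measure = "HR", retry_factor = 100, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(n_pairs >= 0, prop_orr >= 0, prop_orr <= 1, tau >= 0,
            rep_se_factor > 0, orr_n_original >= 1, orr_n_replication >= 1,
            alpha > 0, alpha < 1, retry_factor >= 1,
            length(orr_p_range) == 2, all(orr_p_range > 0), all(orr_p_range < 1))
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic table of study pairs
#'
#' Ratio pairs: a true log effect theta ~ N(mu, tau^2) is drawn per pair;
#' the original estimate is N(theta, se^2) and the replication
#' N(theta, (f se)^2) with f the replication SE factor; points are
#' exponentiated and 95% CIs built as estimate +/- 1.96 se on the log
#' scale, so both sides are unbiased on the log scale and the interval
#' is exact. ORR pairs: a true response rate is drawn, binomial responder
#' counts for both trials, and Clopper-Pearson 95% intervals. With the
#' significance filter on, ratio pairs are redrawn until the original's
#' reconstructed two-sided p is below alpha (generation aborts with an
#' error when the retry budget is exhausted, which signals a filter that
#' rejects essentially everything).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{pair_table}} with \code{n_pairs} rows.
#' @examples
#' pairs <- simulate_pairs(sim_config(n_pairs = 6, seed = 42))
#' @export
simulate_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_orr <- round(config$prop_orr * config$n_pairs)
  n_ratio <- config$n_pairs - n_orr
  z <- stats::qnorm(0.975)

  with_seed(config$seed, {
    rows <- vector("list", config$n_pairs)
    budget <- ceiling(config$retry_factor * max(1, config$n_pairs))
    draws <- 0L
    for (i in seq_len(n_ratio)) {
      repeat {
        draws <- draws + 1L
        if (draws > budget) {
          stop("generation exhausted: the significance filter rejected ",
               budget, " consecutive draws")
        }
        theta <- stats::rnorm(1, config$mu, config$tau)
        se_o <- stats::rlnorm(1, config$se_meanlog, config$se_sdlog)
        est_o <- stats::rnorm(1, theta, se_o)
        orig_sig <- abs(est_o / se_o) > z
        if (!config$select_original_significant || orig_sig) break
      }
      se_r <- config$rep_se_factor * se_o
      est_r <- stats::rnorm(1, theta, se_r)
      rows[[i]] <- data.frame(
        pair_id = sprintf("sim_ratio_%04d", i), measure = config$measure,
        orig_point = exp(est_o), orig_lo = exp(est_o - z * se_o),
        orig_hi = exp(est_o + z * se_o),
        rep_point = exp(est_r), rep_lo = exp(est_r - z * se_r),
        rep_hi = exp(est_r + z * se_r),
        direction = config$direction,
        original_significant = if (orig_sig) "significant" else "nonsignificant",
        order_inverted = FALSE, original_design = "RCT",
        intervention_type = "pharmacological",
        citations_per_year = NA_real_, original_n = NA_real_,
        original_p = NA_real_, stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_orr)) {
      p_true <- stats::runif(1, config$orr_p_range[1], config$orr_p_range[2])
      x_o <- stats::rbinom(1, config$orr_n_original, p_true)
      x_r <- stats::rbinom(1, config$orr_n_replication, p_true)
      ci_o <- clopper_pearson(x_o, config$orr_n_original)
      ci_r <- clopper_pearson(x_r, config$orr_n_replication)
      rows[[n_ratio + j]] <- data.frame(
        pair_id = sprintf("sim_orr_%04d", j), measure = "ORR",
        orig_point = x_o / config$orr_n_original, orig_lo = ci_o[["lo"]],
        orig_hi = ci_o[["hi"]],
        rep_point = x_r / config$orr_n_replication, rep_lo = ci_r[["lo"]],
        rep_hi = ci_r[["hi"]],
        direction = config$direction,
        original_significant = "not_applicable",
        order_inverted = FALSE, original_design = "phase1",
        intervention_type = "pharmacological",
        citations_per_year = NA_real_, original_n = as.numeric(config$orr_n_original),
        original_p = NA_real_, stringsAsFactors = FALSE)
    }
    df <- if (config$n_pairs) do.call(rbind, rows) else
      utils::read.csv(text = paste(PAIR_COLUMNS, collapse = ","),
                      colClasses = "character")
    pair_table(df)
  })
}

#' Chance rate of non-overlapping CIs for two estimates of the same effect
#'
#' Simulates pairs of independent normal estimates of one common true
#' effect, with standard errors (se, se * se_ratio), and returns the
#' fraction whose 95% confidence intervals are disjoint. Two intervals
#' x_i +/- 1.96 se_i are disjoint exactly when |x1 - x2| exceeds
#' 1.96 (se1 + se2); for equal standard errors the rate converges to
#' 2 (1 - Phi(2 * 1.96 / sqrt(2))), about 0.56% -- the false-failure rate
#' of the CI-overlap replication criterion for identical effects.
#'
#' @param se_ratio replication SE as a multiple of the original's.
#' @param n_sims number of simulated pairs.
#' @param seed integer seed.
#' @return the simulated non-overlap proportion.
#' @examples
#' overlap_false_failure_rate(1, 1e5, seed = 1)  # ~0.0056
#' @export
overlap_false_failure_rate <- function(se_ratio = 1, n_sims, seed = 1) {
  stopifnot(se_ratio > 0, n_sims >= 1)
  z <- stats::qnorm(0.975)
  with_seed(seed, {
    d <- stats::rnorm(n_sims, 0, sqrt(1 + se_ratio^2))
    mean(abs(d) > z * (1 + se_ratio))
  })
}
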