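test_that("meta tables validate their inputs", {
  df <- data.frame(study_id = c("a", "b"), year = c(2005, 2010), n = c(100, 200),
                   log_effect = c(-0.2, -0.3), se = c(0.1, 0.2),
                   is_index = c(TRUE, FALSE))
  expect_s3_class(meta_table(df), "meta_table")
  expect_error(meta_table(df[0, ]), "at least one study")
  df2 <- df; df2$is_index <- TRUE
  expect_error(meta_table(df2), "at most one index")
  df3 <- df; df3$se[1] <- NA
  expect_error(meta_table(df3), "neither 2x2 counts nor")
  df4 <- df; df4$se[1] <- -0.1
  expect_error(meta_table(df4), "positive")
})

test_that("two identical studies pool to themselves with zero heterogeneity", {
  set <- meta_table(data.frame(study_id = c("a", "b"), year = c(2005, 2006),
                               n = c(100, 100), log_effect = c(-0.3, -0.3),
                               se = c(0.1, 0.1), is_index = c(FALSE, FALSE)))
  pooled <- pool_random_effects(set, "HR")
  expect_equal(pooled$point, exp(-0.3), tolerance = 1e-12)
  expect_equal(attr(pooled, "tau2"), 0)
  expect_equal(attr(pooled, "Q"), 0)
})

test_that("random-effects pooling matches the brute-force moment oracle and metafor", {
  yi <- c(-0.41, -0.10, -0.62)
  vi <- c(0.02, 0.05, 0.09)
  set <- meta_table(data.frame(study_id = c("s1", "s2", "s3"),
                               year = c(2004, 2008, 2012), n = c(300, 150, 90),
                               log_effect = yi, se = sqrt(vi),
                               is_index = c(TRUE, FALSE, FALSE)))
  pooled <- pool_random_effects(set, "RR")
  oracle <- dl_oracle(yi, vi)
  expect_equal(log(pooled$point), oracle$mu, tolerance = 1e-10)
  expect_equal(attr(pooled, "tau2"), oracle$tau2, tolerance = 1e-10)
  expect_equal(log(pooled$hi) - log(pooled$point),
               stats::qnorm(0.975) * oracle$se, tolerance = 1e-10)
  rma <- metafor::rma(yi = yi, vi = vi, method = "DL")
  expect_equal(log(pooled$point), as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(attr(pooled, "tau2"), rma$tau2, tolerance = 1e-8)
})

test_that("count-based pooling uses per-study 2x2 effects and the MH common step", {
  set <- meta_table(data.frame(
    study_id = c("t1", "t2"), year = c(2005, 2010), n = c(200, 200),
    events_a = c(10, 15), total_a = c(100, 100),
    events_b = c(20, 15), total_b = c(100, 100),
    is_index = c(FALSE, FALSE)))
  pooled <- pool_random_effects(set, "RR")
  expect_equal(attr(pooled, "mh_common"),
               mh_rr_oracle(c(10, 15), c(100, 100), c(20, 15), c(100, 100)),
               tolerance = 1e-12)
  # per-study effects identical to direct 2x2 computation, pooled via DL
  y <- log(c(0.5, 1)); v <- c(1/10 - 1/100 + 1/20 - 1/100, 2 * (1/15 - 1/100))
  expect_equal(log(pooled$point), dl_oracle(y, v)$mu, tolerance = 1e-10)
})

test_that("equal-variance studies with no heterogeneity pool to the log-scale mean", {
  yi <- c(-0.30, -0.32, -0.28)  # Q < k-1 so tau2 truncates to 0
  set <- meta_table(data.frame(study_id = paste0("s", 1:3), year = 2005:2007,
                               n = rep(100, 3), log_effect = yi, se = rep(0.2, 3),
                               is_index = c(TRUE, FALSE, FALSE)))
  pooled <- pool_random_effects(set, "HR")
  expect_equal(attr(pooled, "tau2"), 0)
  expect_equal(log(pooled$point), mean(yi), tolerance = 1e-12)
})

test_that("leave-one-out of a 2-study set returns the other study verbatim", {
  set <- meta_table(data.frame(study_id = c("index", "other"), year = c(2008, 2012),
                               n = c(500, 800), log_effect = c(-0.5, -0.2),
                               se = c(0.12, 0.08), is_index = c(TRUE, FALSE)))
  loo <- leave_one_out(set, "HR")
  expect_equal(log(loo$point), -0.2, tolerance = 1e-12)
  expect_identical(attr(loo, "k"), 1L)
  expect_equal(log(loo$hi), -0.2 + stats::qnorm(0.975) * 0.08, tolerance = 1e-12)
})

test_that("leave-one-out refits the remaining studies and validates the index", {
  yi <- c(-0.41, -0.10, -0.62); vi <- c(0.02, 0.05, 0.09)
  set <- meta_table(data.frame(study_id = c("hc", "r1", "r2"), year = c(2004, 2008, 2012),
                               n = c(300, 150, 90), log_effect = yi, se = sqrt(vi),
                               is_index = c(TRUE, FALSE, FALSE)))
  loo <- leave_one_out(set, "RR")
  oracle <- dl_oracle(yi[-1], vi[-1])
  expect_equal(log(loo$point), oracle$mu, tolerance = 1e-10)
  no_index <- set; no_index$is_index <- FALSE
  expect_error(leave_one_out(meta_table(as.data.frame(no_index))), "no index")
  only_index <- meta_table(data.frame(study_id = "hc", year = 2004, n = 300,
                                      log_effect = -0.4, se = 0.1, is_index = TRUE))
  expect_error(leave_one_out(only_index), "nothing remains")
})

test_that("pooled estimates stay within the convex hull of study effects", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    yi <- stats::rnorm(k, -0.3, 0.5); vi <- stats::runif(k, 0.01, 0.2)
    set <- meta_table(data.frame(study_id = paste0("s", 1:k), year = 2000 + 1:k,
                                 n = rep(100, k), log_effect = yi, se = sqrt(vi),
                                 is_index = FALSE))
    pooled <- pool_random_effects(set, "RR")
    expect_gte(log(pooled$point), min(yi) - 1e-12)
    expect_lte(log(pooled$point), max(yi) + 1e-12)
  }
})

test_that("removing a study at the pooled effect leaves the point fixed when tau2 = 0", {
  yi <- c(-0.3, -0.3, -0.3); vi <- c(0.04, 0.02, 0.09)
  set <- meta_table(data.frame(study_id = c("hc", "r1", "r2"), year = 2004:2006,
                               n = rep(100, 3), log_effect = yi, se = sqrt(vi),
                               is_index = c(TRUE, FALSE, FALSE)))
  before <- pool_random_effects(set, "RR")
  after <- leave_one_out(set, "RR")
  expect_equal(log(after$point), log(before$point), tolerance = 1e-12)
})

test_that("contribution fraction and the half-sample eligibility rule", {
  set <- meta_table(data.frame(study_id = c("hc", "a", "b"), year = c(2005, 2003, 2008),
                               n = c(100, 250, 150), log_effect = c(-0.3, -0.2, -0.25),
                               se = rep(0.1, 3), is_index = c(TRUE, FALSE, FALSE)))
  expect_equal(contribution_fraction(set), 100 / 500)
  solo <- meta_table(data.frame(study_id = "hc", year = 2005, n = 100,
                                log_effect = -0.3, se = 0.1, is_index = TRUE))
  expect_equal(contribution_fraction(solo), 1)
})

test_that("preceding-mass comparison is strict and year-based", {
  base <- data.frame(study_id = c("hc", "a", "b"), year = c(2010, 2005, 2007),
                     n = c(100, 300, 200), log_effect = c(-0.3, -0.2, -0.25),
                     se = rep(0.1, 3), is_index = c(TRUE, FALSE, FALSE))
  expect_true(preceding_mass_exceeds(meta_table(base)))   # all earlier
  later <- base; later$year <- c(2010, 2012, 2015)
  expect_false(preceding_mass_exceeds(meta_table(later))) # all later
  tied <- base; tied$year <- c(2010, 2005, 2015); tied$n <- c(100, 200, 200)
  expect_false(preceding_mass_exceeds(meta_table(tied)))  # equal masses: strict
})

test_that("replication selection honours tiers, sample size and the meta rule", {
  cands <- data.frame(study_id = c("rct1", "meta1"), tier = c("RCT", "meta_analysis"),
                      n = c(400, 2000), contribution = c(NA, 0.6),
                      stringsAsFactors = FALSE)
  # higher-tier RCT replicates a phase-1 (uncontrolled) original
  chosen <- select_replication(list(tier = "uncontrolled", n = 30), cands)
  expect_identical(chosen$study_id, "rct1")
  # a meta-analysis dominated by the index study is ineligible
  only_meta <- cands[cands$tier == "meta_analysis", , drop = FALSE]
  expect_null(select_replication(list(tier = "RCT", n = 500), only_meta))
  # same tier needs equal-or-larger n (boundary inclusive)
  same <- data.frame(study_id = "rct2", tier = "RCT", n = 500,
                     contribution = NA, stringsAsFactors = FALSE)
  expect_identical(select_replication(list(tier = "RCT", n = 500), same)$study_id,
                   "rct2")
  expect_null(select_replication(list(tier = "RCT", n = 501), same))
  # largest n wins; exact ties break lexicographically
  pool <- data.frame(study_id = c("zeta", "alpha", "mid"), tier = "RCT",
                     n = c(900, 900, 700), contribution = NA,
                     stringsAsFactors = FALSE)
  expect_identical(select_replication(list(tier = "uncontrolled", n = 40), pool)$study_id,
                   "alpha")
})

test_that("meta CSV round trip preserves the study table", {
  set <- data.frame(study_id = c("hc", "a"), year = c(2005, 2008), n = c(100, 300),
                    events_a = c(10, NA), total_a = c(50, NA),
                    events_b = c(20, NA), total_b = c(50, NA),
                    log_effect = c(NA, -0.2), se = c(NA, 0.1),
                    is_index = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(set, path, row.names = FALSE, na = "")
  back <- read_meta_csv(path)
  expect_s3_class(back, "meta_table")
  expect_equal(back$log_effect, set$log_effect)
  expect_identical(back$is_index, set$is_index)
  expect_equal(attr(back, "has_counts"), c(TRUE, FALSE))
})
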