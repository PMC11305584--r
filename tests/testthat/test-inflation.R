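test_that("pair inflation ratios follow the direction and inversion rules", {
  pairs <- highly_cited_pairs()
  row <- function(id) pairs[pairs$pair_id == id, ]
  expect_equal(pair_ratio(row("SHARP"))$ratio, 1)
  expect_equal(pair_ratio(row("Brahmer2012"))$ratio, 0.13 / 0.27, tolerance = 1e-12)
  # inverted pair: reciprocal of the favorable-orientation ratio
  esc <- pair_ratio(row("ESCAPE"), apply_inversion = TRUE)
  expect_equal(esc$ratio, 1.37 / 1.86, tolerance = 1e-12)
  expect_true(esc$inverted)
  esc0 <- pair_ratio(row("ESCAPE"), apply_inversion = FALSE)
  expect_equal(esc0$ratio, 1.86 / 1.37, tolerance = 1e-12)
  expect_equal(esc$ratio * esc0$ratio, 1, tolerance = 1e-12)
  # non-inverted pairs are identical under both settings
  expect_equal(pair_ratio(row("HERA"), TRUE)$ratio,
               pair_ratio(row("HERA"), FALSE)$ratio)
})

test_that("coining transforms estimates to the unfavorable orientation", {
  orr <- coin_estimate(effect_estimate(0.38, 0.25, 0.44, "ORR"))
  expect_equal(c(orr$point, orr$lo, orr$hi), c(0.62, 0.56, 0.75))
  or <- coin_estimate(effect_estimate(2, 1, 4, "OR"))
  expect_equal(c(or$point, or$lo, or$hi), c(0.5, 0.25, 1))
  rr <- coin_estimate(effect_estimate(0.5, 0.3, 0.8, "RR"),
                      counts = list(events_a = 20, total_a = 100,
                                    events_b = 40, total_b = 100))
  expect_equal(rr$point, (80 / 100) / (60 / 100), tolerance = 1e-12)
  expect_error(coin_estimate(effect_estimate(0.5, 0.3, 0.8, "RR")), "counts")
  expect_error(coin_estimate(effect_estimate(0.5, 0.3, 0.8, "HR")), "ORR, OR and RR")
})

test_that("OR coining leaves a pair's inflation ratio unchanged; ORR coining does not", {
  df <- as.data.frame(one_pair(measure = "OR", direction = "favorable"))
  df$orig_point <- 3; df$orig_lo <- 1.5; df$orig_hi <- 6
  df$rep_point <- 2; df$rep_lo <- 1.2; df$rep_hi <- 3.4
  or_pair <- pair_table(df)
  plain <- inflation_records(or_pair, coin = FALSE)
  coined <- inflation_records(or_pair, coin = TRUE)
  expect_equal(coined$ratio, plain$ratio, tolerance = 1e-12)
  expect_true(coined$coined)

  df2 <- as.data.frame(one_pair(measure = "ORR", direction = "favorable",
                                sig = "not_applicable", design = "phase1",
                                point = 0.4, lo = 0.3, hi = 0.5))
  df2$rep_point <- 0.2; df2$rep_lo <- 0.15; df2$rep_hi <- 0.26
  orr_pair <- pair_table(df2)
  plain2 <- inflation_records(orr_pair, coin = FALSE)
  coined2 <- inflation_records(orr_pair, coin = TRUE)
  expect_equal(plain2$ratio, 0.4 / 0.2)
  expect_equal(coined2$ratio, 0.8 / 0.6, tolerance = 1e-12)
})

test_that("coined analyses exclude favorable risk-ratio pairs lacking counts", {
  pairs <- highly_cited_pairs()
  expect_warning(recs <- inflation_records(pairs, coin = TRUE),
                 "MR-CLEAN, ESCAPE")
  expect_identical(nrow(recs), 22L)
  expect_false(any(c("MR-CLEAN", "ESCAPE") %in% recs$pair_id))
})

test_that("inflation summaries are geometric means with t intervals", {
  recs <- data.frame(log_ratio = log(c(2, 0.5)), design = c("RCT", "RCT"))
  s <- summarize_inflation(recs)
  expect_equal(s$mean_ratio, 1)
  expect_equal(unname(s$ci[["lo"]] * s$ci[["hi"]]), 1, tolerance = 1e-10)

  expect_warning(z <- summarize_inflation(data.frame(log_ratio = c(0, 0, 0),
                                                     design = rep("RCT", 3))),
                 "zero variance")
  expect_equal(z$mean_ratio, 1)
  expect_equal(z$p, 1)

  one <- summarize_inflation(data.frame(log_ratio = 0.3, design = "RCT"))
  expect_equal(one$mean_ratio, exp(0.3))
  expect_true(is.na(one$p))
  expect_error(summarize_inflation(data.frame(log_ratio = numeric(),
                                              design = character())), "no records")
})

test_that("summaries are permutation and reciprocal invariant", {
  set.seed(11)
  lr <- stats::rnorm(12, 0.1, 0.4)
  recs <- data.frame(log_ratio = lr, design = "RCT")
  perm <- data.frame(log_ratio = sample(lr), design = "RCT")
  recip <- data.frame(log_ratio = -lr, design = "RCT")
  s <- summarize_inflation(recs)
  expect_equal(summarize_inflation(perm)$mean_ratio, s$mean_ratio)
  expect_equal(summarize_inflation(recip)$mean_ratio, 1 / s$mean_ratio,
               tolerance = 1e-12)
  expect_equal(summarize_inflation(recip)$p, s$p, tolerance = 1e-12)
})

test_that("bundled-pair inflation reproduces the published sensitivity rows", {
  pairs <- highly_cited_pairs()
  # no publication-order inversion: the geometric mean rounds to 1.10
  no_inv <- summarize_inflation(inflation_records(pairs, apply_inversion = FALSE))
  expect_equal(round(no_inv$mean_ratio, 2), 1.10)
  expect_equal(no_inv$n, 24)
  # subgroups of the same analysis
  expect_equal(round(summarize_inflation(
    inflation_records(pairs, apply_inversion = FALSE), "phase1")$mean_ratio, 2), 1.01)
  expect_equal(round(summarize_inflation(
    inflation_records(pairs, apply_inversion = FALSE), "RCT")$mean_ratio, 2), 1.14)
  # coined, no inversion
  coined <- suppressWarnings(inflation_records(pairs, apply_inversion = FALSE,
                                               coin = TRUE))
  expect_equal(round(summarize_inflation(coined)$mean_ratio, 2), 1.14)
  expect_equal(round(summarize_inflation(coined, "phase1")$mean_ratio, 2), 1.17)
  expect_equal(round(summarize_inflation(coined, "RCT")$mean_ratio, 2), 1.12)
  # main analysis: rounding of published inputs leaves only a band
  main <- summarize_inflation(inflation_records(pairs, apply_inversion = TRUE))
  expect_gt(main$mean_ratio, 0.95)
  expect_lt(main$mean_ratio, 1.15)
  expect_gt(main$p, 0.05)
})

test_that("the four-analysis table is internally consistent", {
  pairs <- highly_cited_pairs()
  tab <- inflation_analyses(pairs)
  expect_setequal(unique(tab$analysis),
                  c("main", "publication_order", "coining",
                    "publication_order_coining"))
  expect_identical(tab$n[tab$analysis == "main" & tab$subgroup == "all"], 24L)
  expect_identical(tab$n[tab$analysis == "coining" & tab$subgroup == "all"], 22L)
  # each all-row mean is reproducible from its records
  po <- tab[tab$analysis == "publication_order" & tab$subgroup == "all", ]
  expect_equal(po$mean_ratio,
               summarize_inflation(inflation_records(pairs, FALSE))$mean_ratio)
})
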