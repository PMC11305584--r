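# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written from the defining formulas /
# enumerations, not by calling the code under test.

# DerSimonian-Laird random-effects pooling straight from the moment formulas
dl_oracle <- function(yi, vi) {
  k <- length(yi)
  wi <- 1 / vi
  ybar <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - ybar)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
  ws <- 1 / (vi + tau2)
  list(mu = sum(ws * yi) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2, Q = Q)
}

# Mantel-Haenszel common risk ratio from the textbook weight form
mh_rr_oracle <- function(a, n1, c_, n2) {
  N <- n1 + n2
  sum(a * n2 / N) / sum(c_ * n1 / N)
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins, summing probabilities <= observed (with a
# tiny tolerance for float comparison, as fisher.test uses internally)
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(a) {
    choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  }, numeric(1))
  obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled (tie-free) values to the first group
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  obs <- u_stat(seq_len(m))
  combs <- utils::combn(length(pooled), m)
  us <- apply(combs, 2, u_stat)
  mu <- m * (length(y)) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# binomial tail bisection for Clopper-Pearson bounds (independent of qbeta)
cp_bisect_oracle <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  f_lo <- function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2
  f_hi <- function(p) stats::pbinom(x, n, p) - alpha / 2
  lo <- if (x == 0) 0 else stats::uniroot(f_lo, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else stats::uniroot(f_hi, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo = lo, hi = hi)
}

# a minimal single synthetic pair for degenerate-input tests
one_pair <- function(point = 0.7, lo = 0.5, hi = 0.9, measure = "HR",
                     direction = "unfavorable", sig = "significant",
                     design = "RCT", inverted = FALSE, id = "toy") {
  pair_table(data.frame(
    pair_id = id, measure = measure,
    orig_point = point, orig_lo = lo, orig_hi = hi,
    rep_point = point, rep_lo = lo, rep_hi = hi,
    direction = direction, original_significant = sig,
    order_inverted = inverted, original_design = design,
    intervention_type = "pharmacological",
    citations_per_year = NA_real_, original_n = NA_real_,
    original_p = NA_real_, stringsAsFactors = FALSE))
}
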