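---
title: "Assessing replication of clinical effect estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing replication of clinical effect estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicheck)
```

## The problem

When a widely cited clinical trial is later re-examined — by a larger trial,
or by a meta-analysis of all comparable studies — did the original finding
hold up? replicheck operationalises that question for pairs of effect
estimates. Each pair couples an original study's published effect (an odds
ratio, relative risk, hazard ratio, incidence rate ratio, or — for
uncontrolled phase 1 oncology trials — an objective response rate) with the
corresponding estimate from its best available replication, and the package
scores the pair under several complementary notions of replication success.

Two ideas underpin everything:

1. **Published intervals carry the inferential information.** For a ratio
   measure reported as point $[L, U]$ at the 95% level, the log-scale
   standard error is reconstructed as $(\ln U - \ln L)/3.92$, and a
   two-sided p-value follows from $z = \ln(\text{point})/\mathrm{SE}$ under
   the standard normal. This assumes the interval was (at least
   approximately) symmetric on the log scale, which holds for Wald-type
   intervals universally used with these measures.
2. **No single criterion captures "replication".** Statistical significance
   in the same direction ignores magnitude; CI overlap ignores thresholds;
   point-in-interval containment penalises precise replications. The
   package computes all of them and treats significance-plus-overlap as the
   primary aggregate.

## Replication criteria

For each pair the package evaluates:

- **Significance concordance** — the replication reaches two-sided
  p < $\alpha$ (default 0.05, configurable) with its effect on the same
  side of the null as the original. Only pairs whose original was itself a
  significant controlled comparison are scored; uncontrolled phase 1
  originals carry no test, and initially non-significant originals are
  skipped in the main analysis because failure to reject is not evidence
  of equivalence. A sensitivity variant (`include_negatives = TRUE`) scores
  them too, counting a non-significant original as concordant only with a
  non-significant replication.
- **CI overlap** — the two 95% intervals are non-disjoint. Boundaries are
  inclusive (closed intervals): two intervals sharing an endpoint overlap.
  This matters in practice because published bounds are rounded; with
  two-decimal reporting, ties at the boundary occur and the inclusive rule
  is the one consistent with treating printed values as the data.
- **Containment** — the replication's point inside the original's interval
  (forward), and vice versa (reverse). Reverse containment is reported but
  is an excessively strict criterion whenever replications are much larger
  than originals, since their intervals shrink with sample size.
- **Aggregate** (primary) — CI overlap AND significance concordance not
  failed. A pair with no applicable significance test is judged by overlap
  alone; `"not_applicable"` never counts as failure.

Criterion-level rates come with binomial confidence intervals. The Wilson
score interval is the default — it is well-behaved at the small
denominators (15–24) these analyses produce — with the simple Wald interval
available for comparison; reports record which estimator was used.

## Effect-size inflation

Inflation is measured per pair as a ratio oriented so that values above 1
mean the earlier study showed the stronger effect: replication/original for
unfavorable outcomes (death, progression — effectiveness grows as the
measure shrinks), original/replication for favorable ones (response,
improvement). Ratios are analysed on the natural-log scale — the only scale
on which "no systematic inflation" is a symmetric null — via their mean, a
t-based 95% CI, and a one-sample t-test against zero, all exponentiated
back for reporting.

Two bookkeeping adjustments, each with a sensitivity analysis:

- **Publication order.** When the replication is a meta-analysis in which
  most of the pooled sample size *predates* the highly cited study, the
  highly cited study is effectively the replication, and the ratio is
  inverted (`order_inverted` flag; `preceding_mass_exceeds()` derives it
  for new data). The "publication_order" analysis drops the inversion.
- **Coining.** Favorable outcomes can instead be converted to unfavorable
  complements: ORR to 1−ORR, OR to 1/OR, RR to the complementary-outcome RR
  (which needs per-arm counts; favorable RR pairs without counts are
  excluded from coined analyses with a warning). Coining an OR provably
  leaves the pair ratio unchanged; coining an ORR does not, which is why
  the coined phase-1 column differs from the uncoined one.

In the bundled data the coined analyses therefore run on 22 of 24 pairs:
the two favorable RR pairs report only the published ratio estimates, not
the per-arm counts a complementary-outcome RR needs.

Degenerate inputs are handled explicitly rather than failing: a single
record yields a mean with NA interval and p; a zero-variance set of log
ratios yields p = 1 with a warning (the defensible limit of the t-test,
and what toy all-identical inputs produce).

## Leave-one-out meta-analysis

Meta-analytic replications that include the original study are not
independent of it. `leave_one_out()` removes the index study and re-pools
the remainder under a DerSimonian-Laird random-effects model: per-study log
effects from 2x2 counts where available (otherwise supplied log effects and
SEs), the method-of-moments $\tau^2$ truncated at zero, and
inverse-variance weights $1/(v_i + \tau^2)$. When every study carries
counts, the Mantel-Haenszel common-effect estimate is also computed and
attached, mirroring the common-effect step of the Mantel-Haenszel
random-effects procedure. Two deliberate rules:

- A two-study meta-analysis minus its index study *is* the other study:
  the estimate is returned verbatim, with no single-study "refit".
- No continuity corrections anywhere: a zero cell is an error, and callers
  who want 0.5-corrections must apply them to the counts explicitly, so
  the choice is visible in the data rather than buried in a default.

Replication eligibility rules are implemented in `select_replication()`:
a candidate must be of a strictly higher evidence tier (meta-analysis >
RCT > cohort > uncontrolled) or the same tier with at least the original's
sample size; meta-analyses additionally need the index study to contribute
under half the pooled sample. Largest sample size wins; exact ties break
lexicographically by study id — an arbitrary but deterministic rule chosen
so that pipelines are reproducible (consensus-based tie-breaking cannot be
automated).

## Predictors of replicability

`compare_predictors()` contrasts replicated and contradicted pairs under a
chosen criterion: design and intervention type by Fisher's exact test
(two-sided by summation of hypergeometric probabilities no larger than the
observed table's), and citations per year, sample size and original
p-value by the Mann-Whitney U test (exact by enumeration for combined
n ≤ 10 without ties, normal approximation with tie correction otherwise).
Pairs missing a predictor are dropped from that comparison only; an empty
group leaves the comparison undefined (NA) rather than erroring, since
small samples with high replication rates routinely produce empty
contradicted groups. No multiplicity correction is applied across
predictors; with the denominators involved these tests are descriptive.

## The synthetic generator

`simulate_pairs()` generates pair tables with the statistical structure
the analysis assumes, so every pipeline stage can be tested without any
real data, and so the calibration of the criteria can be measured.

For ratio pairs, a true log effect $\theta \sim N(\mu, \tau^2)$ is drawn
per pair; the original estimate is $N(\theta, \mathrm{se}^2)$ and the
replication $N(\theta, (f\,\mathrm{se})^2)$, with 95% CIs built as
$\pm 1.96\,\mathrm{se}$ on the log scale. ORR pairs draw a true response
rate and binomial counts with Clopper-Pearson intervals. Defaults mirror
the bundled dataset: 24 pairs with a 7/24 ORR share; $\mu = -0.45$,
$\tau = 0.35$ (typical protective ratio near 0.64); original log-scale SEs
lognormal with median 0.14 (the bundled originals' CI-derived SEs span
roughly 0.07–0.56); replication SE factor $f = 0.5$ (replications are
pooled or larger studies); phase-1 arms of 30 versus 300 patients with
true rates uniform on [0.15, 0.45]. An optional filter retains only pairs
whose original reaches p < $\alpha$, redrawing up to a configurable budget
(default 100 draws per requested pair) — this is the winner's-curse
mechanism: conditioning on significance inflates the original relative to
its replication even though both estimators are unbiased.

What the generator does *not* emulate: between-study heterogeneity within
a replication meta-analysis (the replication is drawn around the same
$\theta$), correlated originals (two originals sharing a replication),
outcome-measure conversion error, or publication-order structure (all
generated pairs have `order_inverted = FALSE`). Passing tests therefore
validate the scoring machinery and its calibration under the stated
sampling model, not the epistemics of any particular literature.

One numerical subtlety: the log of a binomial proportion has an $O(1/n)$
small-sample bias ($-(1-p)/(2np)$ to first order), so the "mean log
inflation is zero without selection" property is exact only for ratio
pairs; the test suite checks ORR pairs against a bias-aware bound and
ratio pairs against plain Monte-Carlo error.

`overlap_false_failure_rate()` measures the overlap criterion's type 1
error for identical true effects: two intervals
$x_i \pm 1.96\,\mathrm{se}_i$ are disjoint exactly when
$|x_1 - x_2| > 1.96(\mathrm{se}_1 + \mathrm{se}_2)$, giving
$2(1 - \Phi(2 \cdot 1.96/\sqrt{2})) \approx 0.56\%$ for equal SEs — the
false-failure probability the acceptance script re-derives by simulation
(10^6 pairs, a few seconds). The criterion is thus very permissive, which
is why it is combined with significance concordance in the aggregate.

## Numerical and design choices

- The constant 3.92 is kept literally rather than $2\,\Phi^{-1}(0.975)
  = 3.9199$; the difference is far below the rounding noise of published
  intervals, and the round constant is the stated convention.
- Display rounding (whole percents for rates, two decimals for ratios)
  happens only in print methods; stored values keep full precision.
- The inflation analysis from published tables inherits their rounding.
  With the bundled data, the no-inversion analysis is robust to this
  (its geometric mean rounds stably to 1.10), while the inversion-adjusted
  main analysis is sensitive to the exact inversion set and unrounded
  points; the tests pin it to a band around 1 with a non-significant
  t-test rather than to a third digit.
- Reverse containment with inclusive boundaries counts 10 of the bundled
  24 pairs; two of those sit exactly on a rounded interval boundary, so
  counts of 9 or 10 are both defensible readings of the published values.
  The package asserts the rule (closed intervals), not the coincidence.
- Year is the only publication-ordering granularity used by
  `preceding_mass_exceeds()`; same-year studies count on neither side and
  ties resolve to "not exceeding" (strict inequality).

## Problem sizes

The test suite and acceptance script run the bundled 24-pair table
end-to-end, Monte-Carlo checks at 2,000–10,000 simulated pairs, and the
overlap-calibration simulation at 10^5 (tests) to 10^6 (acceptance script)
pairs — sizes at which Monte-Carlo error is comfortably below the
tolerances asserted while the whole suite stays fast on a single CPU.

## Limitations

The package scores published estimates; it cannot repair what publication
selected. Annotations that require judgment — outcome direction,
intervention class, which study is "the" replication — are data supplied
by the analyst, not inferences the package makes, and the bundled table's
annotations follow the published margins (see the per-column documentation
in `highly_cited_pairs()`). P-values reconstructed from intervals inherit
the normal approximation; for very asymmetric published intervals the
reconstruction degrades (the worst bundled case deviates ~7% at one
bound). And with two dozen pairs, predictor comparisons have little power;
they are reported as description, not inference.
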