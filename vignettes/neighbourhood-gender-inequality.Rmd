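---
title: "Measuring neighbourhood-level gender inequality from aggregate census data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neighbourhood-level gender inequality from aggregate census data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gendineq)
```

## The problem

Gender inequality indices are usually computed at the country or state
level, which masks variation between neighbourhoods. Canadian census
dissemination areas (DAs) — the smallest standard census geography, about
400–700 residents — publish sex-disaggregated aggregate counts, so
neighbourhood-level indicators can be built from them directly. This
package implements that pipeline: twelve indicators spanning five
dimensions of gender relations (demographic/household characteristics,
education, income, work/leisure, political participation), a score that
locates each neighbourhood on a male-dominant-to-female-dominant axis per
indicator, a Monte Carlo test of whether the scores genuinely vary across
neighbourhoods, and between-/within-area comparisons.

Because DA-level census extracts are licensed and not redistributable, the
package ships a seeded synthetic census generator that emulates the
structure of such an extract. Every analysis stage runs identically on a
real extract supplied as CSV in the documented schema.

## The gender inequality score

For an indicator with female value $f$ and male value $m$ (sex-specific
proportions, or mean employment incomes in thousand CAD), the score of a
DA is

$$s = \frac{f}{f + m} \in [0, 1].$$

$s = 0.5$ is perfect equality; $s < 0.5$ male dominance; $s > 0.5$ female
dominance. Conventions, all exercised by the tests:

* **Both values zero.** There is no gender difference by definition, so
  the cell is *attributed* $s = 0.5$ and tagged `both_zero`. This occurs
  frequently for rare indicators (decision-making government positions
  especially).
* **One-sided zero values** ($f = 0, m > 0$ or vice versa) are legitimate
  scores of 0 or 1; observed scores span the full unit interval.
* **One-sided zero denominators** (no eligible people of one sex for an
  age-restricted indicator in a mixed-sex DA): that sex's proportion is
  undefined, the cell emits no score, and the drop is logged. Aggregate
  inputs cannot distinguish "no one eligible" from "rate zero", so
  refusing to score is the only defensible choice.

The score is antisymmetric under sex swap ($s(f,m) + s(m,f) = 1$),
invariant to common rescaling, and strictly increasing in $f$ for fixed
$m > 0$; these are enforced as property tests.

## DA universe and exclusions

Three derived flags control eligibility, with deterministic precedence:

1. **Missing data** (checked first): any NA in a field required for a sex
   with nonzero population. Fields of a sex with zero population are
   structurally absent, not missing.
2. **Single-sex population**: no gender comparison is possible; the DA is
   excluded globally.
3. **Zero labour force**: the DA is *retained* but skipped for the two
   indicators whose universe is the labour force (labour force
   participation, employment rate).

Counts in the exclusion log are exhaustive and mutually exclusive, and
filtering is idempotent.

One definitional note: census summaries sometimes print the "employment
rate" as the employed share of the whole population aged 15+, but its
definition here is the employed share *of the labour force*, and the
employment-rate denominator is therefore the labour-force count. Scores
are unaffected in direction, but the two readings differ in level.

## The Monte Carlo heterogeneity test

Observed score variance across DAs mixes real between-neighbourhood
differences with sampling noise, which is large when denominators are a
few hundred people (and smaller still for items collected from 20% of
households). The test asks whether the observed variance exceeds the
noise-only expectation.

Null model ("homogeneous inequality"): every DA shares the same
sex-specific rates. For proportion indicators the pooled rates are
$\hat p_s = \sum_i x_{is} / \sum_i n_{is}$ over eligible DAs; each
replicate redraws $x_{is} \sim \mathrm{Binomial}(n_{is}, \hat p_s)$,
re-scores every DA with the full set of conventions (including the
both-zero attribution), and records the sample variance (denominator
$n-1$) of the replicate's scores. With $R$ replicates the p-value uses the
add-one rule

$$p = \frac{1 + \#\{V_{\mathrm{null}} \ge V_{\mathrm{obs}}\}}{R + 1},
\qquad \tfrac{1}{R+1} \le p \le 1,$$

which never returns zero and is exact for a discrete Monte Carlo test.
Design choices that were genuinely open, fixed as follows:

* **Test statistic**: the sample variance of the DA scores — the simplest
  statistic that quantifies "variation across neighbourhoods".
* **Pooling level**: province-wide across all eligible DAs, not per area
  type, since the headline heterogeneity question is global.
* **Income null**: the DA sex mean is drawn
  $\mathrm{Normal}(\hat\mu_s, \hat\sigma_s/\sqrt{n_i})$, truncated at
  zero, with $\hat\mu_s$ the population-weighted mean of the DA means and
  $\hat\sigma^2_s = \sum_i n_i(\bar x_{is} - \hat\mu_s)^2/(N-1)$, the
  unbiased person-level variance estimator under that null. Estimating
  person-level spread from a naive SD of DA means would double-count the
  $1/\sqrt{n}$ scaling and collapse the null variance.
* **Eligibility symmetry**: DAs excluded from the observed variance
  (zero labour force, undefined proportions) are excluded identically
  from every null replicate.
* **Replicates**: default $R = 999$; the analysis scripts use $R = 199$,
  which already resolves p-values to 0.005 and keeps the full 11,612-DA
  workflow under half a minute.
* **Seeding**: a master seed spawns one substream per replicate (and per
  indicator in `heterogeneity_test_all()`), and DAs are processed in
  `da_id` order, so results are bit-reproducible and invariant to row
  order.

A known limitation: for income, only DA-level means are observable, so
the person-level SD and any real between-DA SD are confounded in
$\hat\sigma_s$. Real between-DA income variation inflates the estimated
null and the income test is conservative (low power). The proportion
indicators do not share this problem because the binomial null variance
is determined by the pooled rate and the denominators alone.

## Between- and within-area comparisons

Scores are non-normal (often bimodal at 0/1 for rare indicators), so
comparisons are rank-based: a Kruskal–Wallis omnibus test across the
three area types, followed — only when the omnibus p falls below
$\alpha = 0.05$, configurable — by all three pairwise Mann–Whitney tests
with Bonferroni adjustment ($p_{\mathrm{adj}} = \min(1, 3p)$). The
U-tests use the tie-corrected normal approximation without continuity
correction, appropriate at thousands of DAs per group; tests verify it
against an exact-enumeration oracle at small sizes (agreement within 0.2,
the documented small-sample approximation gap, while the U statistic
itself is exact).

Within-area structure is probed by the Spearman correlation between each
indicator's score and its own overall (both-sex) level. Indicators with
$|r| \ge 0.4$ — magnitude, because strong negative correlations flag
level-dependence exactly as positive ones do — are stratified into
**population-weighted tertiles** of the overall level: DAs are sorted by
level (ties broken by `da_id`), population is accumulated, and cuts fall
at the DAs whose cumulative population first reaches 1/3 and 2/3 of the
total, the straddling DA going to the lower tertile. Each stratum then
holds a third of the *population* (within one DA), not a third of the
DAs. Boundaries are computed once on the pooled universe and crossed with
area type; the Kruskal–Wallis p-values reported for the tertile grids
compare tertiles *within* each area type (the row-wise reading).

For the overall income level per DA the package uses the
population-weighted mean of the two sex means, the natural recombination
when only sex-specific means are published.

## The synthetic census generator

The generator emulates the structure of a DA-level aggregate extract:

* 400–700 residents per DA (uniform), sex split Binomial(pop, 1/2) — the
  simplest symmetric default.
* Default sex-specific rates at the observed provincial means of the
  twelve indicators (e.g. divorce 11.2% female / 10.1% male, unpaid
  housework 79.8% / 59.1%), so simulated score distributions land in
  realistic territory.
* Denominator universes as fixed shares of the sex population (75% aged
  20+, 80% aged 15+, 68% aged 25+, 40% for households), with
  20%-household items further shrunk by `sampling_fraction_20pct = 0.2`
  before the binomial draw. This reproduces the extra sampling noise of
  sample-based items without modelling census weighting.
* Between-DA heterogeneity injected on the **logit scale of the female
  rate only** (`heterogeneity_sd`, default 0.3 — a moderate spread giving
  roughly ±1.8 percentage points at a 10% rate and ±7 at 50%), keeping
  the null/alternative contrast one-parameter: `heterogeneity_sd = 0` is
  exactly the homogeneous null. A side effect matching real data: DAs
  with higher female rates have both higher scores and higher overall
  levels, so some indicators become level-correlated and pass the
  $|r| \ge 0.4$ gate.
* Income: per-sex DA means Normal with a person-level component
  ($\mathrm{sd}_s/\sqrt{\mathrm{pop}_s}$, defaults 15 and 25 thousand
  CAD — plausible person-level income spreads) plus a between-DA
  component (`sd_between`, default 2), truncated at zero. `sd_between =
  0` reproduces the income null exactly.
* Pathologies by position, deterministically: the first `n_missing` DAs
  get NA required fields (genuinely absent, not zero), the next
  `n_single_sex` alternate female-/male-only, the next `n_zero_labour`
  have an empty labour force.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring DAs, household structure, census weighting internals, real
area-type geography (labels are drawn independently of the rates, so no
between-area score differences are planted by default), and the exact
prevalence of both-zero cells in rare indicators. Passing tests therefore
demonstrate the pipeline's statistical behaviour under a clean
data-generating process, not agreement with any particular census
extract.

## Calibration and power, as verified by the test suite

At the study conditions (200 DAs of 400–700 residents, $R = 199$, a
proportion indicator near 30%), the acceptance tests check over 200
simulated datasets that the null rejection rate at $\alpha = 0.05$ stays
inside the binomial band $[0.02, 0.09]$ and that the p-values pass a
Kolmogorov–Smirnov uniformity check at $\alpha = 0.01$; with a planted
logit-scale SD of 0.5 the rejection rate exceeds 0.9 over 100 seeds, and
power is monotone over heterogeneity $\{0, 0.2, 0.5\}$ on common seeds.
The analysis scripts run the full pipeline at the 11,612-DA scale.

## Numerical conventions

* Quartiles/IQRs: `stats::quantile(type = 8)`, the median-unbiased
  linear-interpolation rule, fixed so summaries are reproducible bit for
  bit.
* Score SDs and variances use the $n-1$ denominator throughout.
* Scores are kept at full precision internally; rendered tables round
  scores to 2 decimals, percentages to 1, and print p-values below the
  0.01/0.001 cutoffs as "< 0.01" / "< 0.001" while the CSVs keep raw
  values.
* Degenerate rank tests (all values tied) are reported as $H = 0, p = 1$:
  no rank information, no evidence of difference.
* All random draws flow from explicit integer seeds; every result object
  records the seed that produced it.
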