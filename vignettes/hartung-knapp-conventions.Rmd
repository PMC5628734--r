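---
title: "Methods: the Hartung-Knapp modification, dataset taxonomy, and analysis conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Hartung-Knapp modification, dataset taxonomy, and analysis conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkmeta)
```

## The model and the two inference methods

The package works on the conventional random-effects model for study-level
meta-analysis: the estimate from study $i$ is
$Y_i \sim N(\mu, \sigma_i^2 + \tau^2)$, $i = 1,\dots,n$, where the
within-study variances $\sigma_i^2$ are treated as fixed and known, $\mu$
is the average effect of interest, and $\tau^2$ is the between-study
variance. Both inference methods estimate $\tau^2$ first and then treat the
estimate as known, with weights $w_i = 1/(\sigma_i^2 + \hat\tau^2)$ and
pooled estimate $\hat\mu = \sum w_i y_i / \sum w_i$ (identical for both
methods):

* the **standard method** assumes
  $(\hat\mu - \mu)\sqrt{\textstyle\sum w_i} \sim N(0, 1)$, giving
  $\hat\mu \pm z_{1-\alpha/2}/\sqrt{\sum w_i}$ (`ci_standard_re()`); at
  $\hat\tau^2 = 0$ this collapses to the common-effect analysis
  (`ci_common_effect()`, weights $1/\sigma_i^2$);
* the **modified (Hartung-Knapp) method** further computes
  $H^{*2} = \sum w_i (y_i - \hat\mu)^2 / (n-1)$ and assumes
  $(\hat\mu - \mu)\sqrt{\sum w_i}/H^* \sim t_{n-1}$, giving
  $\hat\mu \pm t_{n-1,\alpha/2}\, H^*/\sqrt{\sum w_i}$ (`ci_modified()`).
  We treat $H^*/\sqrt{\sum w_i}$ as the modified method's standard error.
  At $\hat\tau^2 = 0$, $H^*$ equals the Higgins-Thompson $H$.

The t-distribution assumption is exact only if the weights use the true
$\tau^2$; with estimated weights $H^*$ is a random variable whose behaviour
drives everything below. A further ad hoc variant constrains $H^* \ge 1$
(`ci_modified_constrained()`), which forces the modified interval to be at
least as wide as the standard one, at the cost of overcoverage.

Key assumptions inherited by every function: normally distributed study
estimates, known within-study variances, and no selection effects. All
p-values are two-sided, the meta-analytic convention; "95%" quantiles are
computed to double precision rather than rounded to 1.96.

## Between-study variance estimators and their numerics

Three estimators are implemented (`estimate_tau2()`), each returning the
truncation and convergence provenance alongside the value:

* **DerSimonian-Laird** (`tau2_dl()`): the moment estimator
  $(\,Q(0) - (n-1)\,)/(S_1 - S_2/S_1)$ with $u_i = 1/\sigma_i^2$,
  $S_k = \sum u_i^k$, truncated at zero. Closed form, no numerical
  parameters.
* **REML** (`tau2_reml()`): Fisher-scoring fixed-point iteration
  $\tau^2 \leftarrow \sum w_i^2\{(y_i-\hat\mu)^2 - \sigma_i^2\}/\sum w_i^2
  + 1/\sum w_i$, truncated at zero each step, started from the truncated
  DerSimonian-Laird value. Defaults: tolerance $10^{-10}$ on the change in
  $\tau^2$, at most 100 iterations. Fixed points of this map are exactly
  the stationary points of the restricted log-likelihood. Non-convergence
  is reported in the estimate rather than raised, because the empirical
  convention is to *exclude* such datasets, and the caller needs to see
  them to count them. Surveys in this package exclude about 0.1% of
  replicates this way.
* **Paule-Mandel** (`tau2_pm()`): the root of $Q(\tau^2) = n-1$, i.e. the
  $\tau^2$ at which $H^{*2} = 1$. $Q$ is continuous and non-increasing in
  $\tau^2$, so the positive root is unique whenever $Q(0) > n-1$; otherwise
  the estimate is truncated to zero and $H^* < 1$ by construction. The root
  is bracketed by doubling an upper bound from $\max(\mathrm{var}(y),
  \bar\sigma^2)$, solved with `stats::uniroot()` at tolerance $10^{-10}$,
  then polished with up to three Newton steps using the envelope-theorem
  derivative $dQ/d\tau^2 = -\sum w_i^2 (y_i - \hat\mu)^2$. The polish keeps
  $|H^{*2} - 1|$ near machine precision, which matters because the taxonomy
  tests $H^* > 1$.

Two closed-form special cases serve as internal oracles and are exported:
for $n = 2$ all three estimators coincide with
$\{(y_2-y_1)^2 - \sigma_1^2 - \sigma_2^2\}/2$ before truncation
(`tau2_closed_form_n2()`), and when all $\sigma_i^2 = \sigma^2$ they
coincide with $s^2 - \sigma^2$, $s^2$ the sample variance of the estimates
(`equal_variance_closed_form()`). In both cases a positive estimate forces
$H^* = 1$ exactly. The test suite verifies all three iterative estimators
against both closed forms and against an independent implementation
(metafor), to $10^{-7}$ or better.

## The taxonomy

`binary_outcomes()` evaluates four binary outcomes — $\hat\tau^2 > 0$,
$H^* > 1$, modified CI wider than the standard random-effects CI, modified
CI wider than the common-effect CI — and maps them to one of 16 candidate
groups through the fixed allocation implemented in `group_from_outcomes()`
(groups 1-8 have $\hat\tau^2 > 0$; 1-4 and 9-12 have $H^* > 1$; 1-2, 5-6,
9-10, 13-14 have "wider than standard"; odd groups have "wider than
common-effect"). Nine groups are logically impossible; only 1, 5, 7, 8, 9,
13, 16 can occur, and the impossibility arguments are theorems about the
inference functions that the test suite brute-forces on random data.
Estimator-specific reductions (`estimator_exclusions()`): DerSimonian-Laird
cannot give group 9 (truncation implies $H^* < 1$); Paule-Mandel cannot
give 7, 8 or 9 and merges 5 into 1, leaving a 3-group taxonomy; REML admits
all 7. For $n = 2$ or equal variances, every estimator reduces to the same
3 groups (`reduced_group()`).

Numerical choices:

* All width comparisons are strict ("wider than"); ties count as "not
  wider". Genuine ties between a t-based and a z-based interval require
  $H^* = z_{1-\alpha/2}/t_{n-1,1-\alpha/2}$ exactly, a measure-zero event.
* The $H^* > 1$ outcome treats values within $10^{-8}$ of 1 as *not*
  greater: the Paule-Mandel construction gives $H^* = 1$ only to
  root-finding accuracy, and the taxonomy is designed so that the
  strict-versus-non-strict choice at exactly 1 carries no meaning. The
  same band is applied under every estimator, where it can only matter in
  the closed-form cases that also sit at $H^* = 1$ exactly.
* Datasets whose estimates are all *exactly* equal have $H^* = 0$ and a
  zero modified standard error; they are refused by modified inference and
  excluded (and counted) by the harnesses, mirroring empirical practice.
  Near-ties pass through. `detect_degenerate()` is the predicate.

## The six conventions

`analyze()` computes everything once and presents the analysis selected by
a convention: `never` (standard random-effects, collapsing to common-effect
at $\hat\tau^2 = 0$), `always` (modified), `constrain` ($H^* \ge 1$),
`hybrid1` (modified iff $\hat\tau^2 > 0$), `hybrid2` (wider of modified and
standard), `hybrid3` (wider of modified and common-effect). "More
conservative" means *wider interval*, not larger p-value — the
common-effect point estimate differs from the random-effects one, so the
two orderings can disagree. The realized label (e.g. `Mod(t)`, `RE(Z)`,
`CE(t)`) is derived from the data and checked end-to-end against the
hard-coded dispatch grid `expected_label()` in the test suite.

Two genuinely open corners were fixed as follows:

* **Hybrid ties**: if the two candidate intervals have exactly equal width,
  the modified analysis is presented. Ties are measure-zero, and the
  hybrids exist to guard against the modified interval being too short —
  which a tie is not.
* **Labelling at $H^* = 1$**: the modified and conventional standard errors
  then coincide, so `Mod(t)` and `RE(t)` denote the same numbers. The
  dispatch grid names the constrained analysis `Mod(t)` in group 1 and
  `RE(t)` in group 5; since the Paule-Mandel merge places its positive
  estimates (all at $H^* = 1$) in group 1, the realized label follows the
  (merged) group. This is a naming decision only — the presented interval
  is identical either way.

## The synthetic-data generator

`simulate_dataset()` draws $\sigma_i^2$ from a configurable variance law,
$\theta_i \sim N(\mu, \tau^2)$, and $y_i \sim N(\theta_i, \sigma_i^2)$ —
exactly the generating model the inference assumes. Defaults, chosen once
as conventional meta-analysis simulation settings:

* variance law uniform on $(0.1, 1)$ — an order-of-magnitude spread of
  study precisions, typical of log-odds-ratio meta-analyses of moderate
  trials;
* the survey grid (`default_survey_config()`) mixes $n \in \{2, 3, 5, 10,
  20\}$ — dominated by the small sizes where the modification matters —
  with $\tau^2 \in \{0, 0.25, 1, 4\} \times 0.55$ (multiples of the mean
  within-study variance, i.e. homogeneity up to $I^2$-style heavy
  heterogeneity);
* $\mu = 0$ throughout; all four taxonomy outcomes and all interval widths
  are invariant to location shifts of $y$, so $\mu$ only matters for
  coverage studies, which expose it.

Each replicate derives its own RNG substream from `(seed, draw_index)`, so
any flagged dataset can be replayed in isolation and identical configs give
bit-identical surveys.

What the generator deliberately does **not** emulate about real systematic
reviews: within-study variances estimated from the same data as the
estimates (and hence correlated with them, especially for log odds ratios
from small trials), discreteness and zero cells of 2×2 tables, non-normal
true-effect distributions, and selection/publication bias. Passing surveys
therefore demonstrate the *logical* structure — which taxonomy groups can
occur, how often under a clean random-effects world, and that every
convention dispatches as tabulated — not empirical group frequencies for
any real database, which depend on the review mix.

## Harness problem sizes

The shipped test suite runs a 50,000-replicate survey (all three
estimators) for the taxonomy counts, impossibility audit and dispatch-grid
oracle; a 100,000-dataset property sweep for the width orderings; 1,000
datasets per closed-form identity; and a 10,000-replicate coverage study at
$n = 5$, $\tau^2 = 2.2$ (four times the mean within-study variance), which
verifies the directional coverage ordering (standard < modified ≤
constrained, with the modified closest to nominal). At these sizes the
Monte-Carlo standard error of a coverage estimate is below 0.005 and the
rarest observable groups (8 and 9 under REML, at a few per thousand) are
reliably observed. `scripts/acceptance.R` reruns the survey and identity
checks from a user-supplied seed.

## Known limitations

* Only user-supplied effect/variance inputs and the log odds ratio pipeline
  are provided; no risk-ratio, risk-difference or standardized-mean
  pipelines.
* No meta-regression or multivariate extension, no prediction intervals,
  no confidence intervals for $\tau^2$ itself, and no Bayesian
  alternatives.
* The dispatch grid is defined for $\alpha = 0.05$; `alpha` is exposed
  everywhere, but at other levels the width-comparison outcomes (and hence
  group membership) can change, and the grid's correspondence to the
  conventions is not guaranteed.
* Group 8 under DerSimonian-Laird is possible but rare; surveys of the
  default size may legitimately contain zero instances.
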