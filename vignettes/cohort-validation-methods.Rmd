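---
title: "Validating virtual cohorts and planning in-silico trials with cohortval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating virtual cohorts and planning in-silico trials with cohortval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortval)
```

## Scope and data model

`cohortval` compares a *virtual* cohort (synthetic patient records) against a
*real* reference cohort and analyses validated cohorts in one-group and
two-group in-silico trial designs. A cohort is a CSV table with a header row;
each analysis variable is `continuous`, `discrete`, or `time_to_event`. A
time-to-event variable is encoded as a nonnegative time column plus a named
companion 0/1 event-indicator column (1 = event observed, 0 = censored);
ties between events and censorings at the same time are resolved events-first,
the standard product-limit convention. Cells equal to `""` or `"NA"` are
missing; each analysis drops records with missing values in its own variables
(complete-case, with the dropped count logged). A real/virtual pair must share
one variable structure — same names, same kinds; column order may differ and
only triggers a warning, since reordering columns does not change the joint
distribution being compared.

All analyses are carried out under a stated Context of Use and Question of
Interest: free-text documentation of how the computational model is used and
what the simulation is meant to answer. The command-line interface refuses
validation runs without them unless `--no-context` opts out explicitly.

## Univariate and bivariate comparison

The univariate view reports mean, standard deviation (divisor $n-1$
throughout the package), minimum and maximum per variable and cohort, plus
Tukey boxplot statistics: quartiles by linear-interpolation quantiles
(type 7, the R default), whiskers at the most extreme points within
$1.5\,\mathrm{IQR}$ of the quartiles, points beyond flagged as outliers.
The bivariate view computes Spearman rank correlations (average ranks for
ties) between all variable pairs, separately per cohort, on
pairwise-complete records, and attaches the difference matrix
(virtual − real). A constant variable makes the coefficient undefined; such
entries are returned as `NA` and named in `undefined_pairs` rather than
silently set to zero.

## Multivariate comparison

Each record is standardized against *its own* cohort: with per-cohort sample
mean $\bar x$ and sample covariance $S$,

$$ d_i = (x_i - \bar x)^\top S^{-1} (x_i - \bar x). $$

This is the squared Mahalanobis distance from the cohort centre. Two exact
properties anchor the implementation and its tests: with divisor $n-1$,
$\sum_i d_i = p\,(n-1)$ identically, and $d_i$ is invariant under any
invertible affine transformation of the feature block. Under multivariate
normality the $d_i$ are approximately chi-squared; the two cohorts are
compared by pairing linear-interpolation quantiles of $d^{real}$ and
$d^{virtual}$ on a common probability grid (a straight diagonal indicates
compatible multivariate shape) and by overlaying histograms with a
chi-squared reference from `chi2_reference()`.

**Degrees of freedom.** The environment this package re-creates documents
the reference as chi-squared with *number of variables minus one* degrees of
freedom; the classical asymptotic for Mahalanobis squared distances is
$\chi^2_p$. Both are available (`df_mode = "paper"`, the default, gives
$p-1$; `"classical"` gives $p$) and the choice is recorded in the result
rather than hidden. For $p = 1$ the `"paper"` mode yields the degenerate
df = 0 and is kept literal; use `"classical"` there. The QQ pairing between
the two cohorts does not depend on this choice at all.

A singular sample covariance (collinear variables) aborts with the offending
variable pairs named, detected via a Cholesky factorization with a reciprocal
condition bound of $10^{-12}$.

## Variability assessment: bootstrap density bands

The real data is the reference distribution; uncertainty of the virtual
cohort is assessed by resampling it. `bootstrap_density_band()` draws $B$
bootstrap samples of size $n_{virtual}$ with replacement from the virtual
values; each replicate's Gaussian-kernel density is evaluated on a common
grid of 512 equally spaced points spanning the pooled data range extended by
3 bandwidths. The band is the pointwise $(\alpha/2, 1-\alpha/2)$ percentile
envelope across replicates at coverage `level` (default 0.95).

Numerical choices:

- **Bandwidth**: Silverman's rule of thumb,
  $0.9 \min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}$ — the default of the
  ecosystem the original tool was built in — re-estimated per bootstrap
  replicate so the band reflects bandwidth variability too.
- **The bootstrap p-value**: the source methodology counts "the number of
  times that the density of the real data is out of the 95% confidence
  bounds" without stating the denominator. We normalize by the number of
  grid points and label the quantity `outside_fraction` (the `p_value` field
  is an alias). It is a descriptive exceedance fraction, not a calibrated
  test p-value.
- **Deviation rule**: declaring a deviation whenever *any* grid point
  escapes the band would be vacuously sensitive at 512 points, so the flag
  fires when the outside fraction exceeds `deviation_threshold`
  (default 0.05, configurable).
- Everything is a pure function of (inputs, seed); re-runs are bit-identical.

## Trial application

- *Discrete*: Pearson chi-square — goodness of fit against stated
  probabilities (default: equal proportions over observed levels; the
  original tool does not state its null) in one group, homogeneity on the
  group × level table across two groups, levels taken as the union. The
  Yates continuity correction is **off** by default so the 2×2 closed form
  $N(ad-bc)^2/(r_1 r_2 c_1 c_2)$ holds exactly; a flag enables it.
- *Continuous*: two-sample t-test, Welch by default (matching the default of
  the ecosystem the original tool ships in), pooled mode for textbook
  comparisons; the effect summary carries the mean difference and its SE.
- *Time-to-event*: Kaplan–Meier product-limit estimation, and the two-group
  "Kaplan–Meier test" is implemented as the standard log-rank (Mantel–Cox)
  test — the source names no specific test, and log-rank is the field's
  default reading. The statistic is invariant under common monotone time
  transforms and matches `survival::survdiff` to machine precision in the
  test suite (which uses `survival` purely as an independent oracle).

## Sample size under effect-size uncertainty

The fixed-effect formula is the normal-approximation closed form
$n = \lceil 2\sigma^2 (z_{1-\alpha^*} + z_{pow})^2 / \Delta^2 \rceil$ per
group ($\alpha^* = \alpha/2$ two-sided), floored at 2; a $t$-based iterative
refinement is deliberately out of scope — the closed form is reproducible
and its error is below one subject per group at the sizes involved.
`achieved_power()` is its exact inverse
$\Phi(|\Delta|/(\sigma\sqrt{2/n}) - z_{1-\alpha^*})$ (dominant tail, so a
zero effect returns the one-tail size $\alpha^*$).

Uncertainty in the effect is expressed as bounds $0 < l \le u \le 1$ on a
multiplicative shrinkage factor applied to $|\mu_1 - \mu_2|$: a quantity
bounded in $[0,1]$ cannot be the raw mean difference in general, so the
bounds the original interface exposes are read as relative shrinkage. The
source does not state how scenarios are placed between the bounds; we draw
them uniformly at random under a seed (surfaced in the report), with a
deterministic `grid` mode for testing. A lower bound of exactly 0 is
rejected — a zero multiplier means a zero effect and an unbounded sample
size. Each scenario's required $n$ is summarised by
minimum/median/mean/maximum (per group, labelled as such; the source does
not say whether its figures are per group or total), and the power table
reports, for candidate sizes (default: deciles of the scenario sizes), the
fraction of scenarios with achieved power below the threshold (default 0.90,
as the original prints).

## The synthetic-data generator

`synthetic_spec()`/`generate_pair()` state a known ground truth: a
multivariate-normal continuous block (stated mean and positive-definite
covariance), independent categorical variables with stated level
probabilities, and a censored exponential time-to-event variable (event
hazard $r$, censoring hazard $c$; observed time is the minimum, the expected
event fraction is $r/(r+c)$). The virtual cohort is drawn from the perturbed
model (mean + `mean_shift`, covariance × `covariance_scale`). Real and
virtual cohorts use disjoint random sub-streams derived from one master
seed, so changing one cohort's size never perturbs the other's draw.

The CLI fixture defaults — equicorrelation 0.3 across continuous features, a
3-level categorical at 0.5/0.3/0.2, event hazard 0.5 against censoring
hazard 0.2 (≈71% events) — were chosen once as a realistic mildly-correlated
clinical feature block and are not tuned to any test.

What the generator does *not* emulate: statistical-shape-model geometry,
dependence between categorical and continuous features, non-normal marginals,
or informative censoring. A green validation test therefore establishes that
the statistics behave correctly on data satisfying their own assumptions —
not that any particular virtual-cohort generator produces realistic patients.

## Known limitations

- No covariate-adjusted models (Cox, mixed-effects, logistic, ANOVA) — the
  original environment also lacks them — and no correlation-difference
  significance testing or formal multivariate-normality test.
- The bootstrap band is pointwise, not simultaneous: its per-point coverage
  is `level`, while family-wise coverage over 512 points is lower; this
  mirrors the original methodology.
- Reports render to JSON/Markdown/HTML; PDF is delegated to external
  converters. Config files are JSON (no YAML parser is assumed available).
- A discrete level literally equal to `"NA"` cannot be distinguished from a
  missing value under the CSV dialect and will not round-trip.
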