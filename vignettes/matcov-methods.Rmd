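---
title: "Estimating minimally adequate treatment coverage for major depressive disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating minimally adequate treatment coverage for major depressive disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matcov)
```

## The problem

Population mental-health surveys occasionally report what fraction of
people with major depressive disorder (MDD) received *minimally adequate
treatment* (MAT): pharmacotherapy for at least a month with several
physician visits, or a course of at least eight psychotherapy sessions.
Such estimates are sparse — a few dozen studies worldwide — and
heterogeneous: many report proxies (any antidepressant use, any
mental-health-service use) instead of MAT, most collapse the sexes, and
countries without any survey still need estimates. `matcov` implements a
pipeline that turns this kind of evidence base into a coverage surface by
country, age, sex, and year, with draw-based uncertainty:

1. **Crosswalk** — adjust proxy indicators to the MAT reference level,
2. **Sex split** — disaggregate both-sex estimates,
3. **Cascade** — hierarchical meta-regression over the location tree,
4. **Aggregation** — prevalence-weighted treated-case counts with
   percentile uncertainty intervals.

All pooling happens on the logit scale, where proportions are unbounded
and indicator biases act additively.

## Crosswalk: trimmed network meta-analysis on logit differences

Estimates of different indicators measured in the same study for the same
location, sex, age band, and year form matched pairs. For a pair $i$ the
logit difference $y_i = \mathrm{logit}(p^{\mathrm{alt}}_i) -
\mathrm{logit}(p^{\mathrm{MAT}}_i)$ has known sampling variance
$s_i^2$ (delta method, summed over the two members) and is modelled as

$$ y_i = \beta_{\mathrm{AD}}\,[{\rm alt}=\mathrm{AD}]
   + \beta_{\mathrm{ANY}}\,[{\rm alt}=\mathrm{ANY}]
   + \beta_{\mathrm{ANY \times HAQI}}\,[{\rm alt}=\mathrm{ANY}]\,(H_i-100)
   + u_{s(i)} + \varepsilon_i, $$

with study random effects $u_s \sim N(0, \tau^2)$ and
$\varepsilon_i \sim N(0, s_i^2)$. $H_i$ is the Healthcare Access and
Quality Index (HAQI, 0–100) of the pair's country-year, centred at 100 so
the main any-service effect is the bias *in the best-case system*, and the
interaction lets the bias grow as access deteriorates. $\tau^2$ is
profiled by REML; fixed effects are generalized least squares at the
profiled $\tau^2$ (`fit_remr()`; the implementation is cross-checked
against `metafor::rma.mv` in the test suite).

**Trimming.** A fixed 5% of pairs is excluded by iterating: fit on the
included set; score every pair by its marginal negative log-likelihood
contribution $\tfrac12\log 2\pi(s_i^2+\tau^2) + \tfrac12 r_i^2/(s_i^2 +
\tau^2)$; exclude the worst $\lceil 0.05\,n\rceil$; refit until the
excluded set stabilises. Trimming is applied under the full model, before
model selection — the two are not interleaved.

**Backward elimination.** Terms are removed one at a time whenever removal
lowers the BIC (computed from ML fits so likelihoods are comparable across
fixed-effect structures), with the guard that a main effect is never
removed while its interaction is retained; BIC ties are broken by dropping
the larger Wald p value. For *parameter-recovery experiments* the package
fits the full three-term model (`eliminate = FALSE`): averaging
selected-to-zero replicates into a coefficient recovery estimate would
conflate selection with estimation.

Adjustment subtracts the fitted correction on the logit scale and **adds**
the correction's sampling variance, so crosswalked estimates never become
more certain than their inputs.

## Sex split

Both-sex estimates are disaggregated using a two-parameter model on
bias-corrected estimates: $\mathrm{logit}(p_i) = \beta_0 + \beta_1
\phi_i + u_{s(i)} + \varepsilon_i$, where $\phi_i$ is the proportion of
the study's MDD cases who are female (0 for male rows, 1 for female rows,
the reported or prevalence-imputed share for both-sex rows). $\beta_0$ is
therefore the all-male level and $\beta_1$ the female–male logit
difference.

Splitting solves, by bisection on $\mathrm{logit}(p_m)$ to a residual
below $10^{-10}$,

$$ (1-\phi)\,p_m + \phi\,\mathrm{invlogit}(\mathrm{logit}(p_m) +
\beta_1) = p_b, $$

so the case-weighted average of the two output rows reproduces the
observed both-sex mean exactly (the test suite checks this identity to
$10^{-8}$ on every split, and checks the solver against a $10^6$-point
grid search). Each output's logit variance is the parent's plus
$\mathrm{Var}(\beta_1)\,\lvert\phi - \mathbf{1}[\mathrm{female}]\rvert$ —
uncertainty is shared symmetrically around the aggregate and never
shrinks. Degenerate $\phi \in \{0, 1\}$ assigns the whole estimate to the
present sex. The sex model's trimming fraction defaults to 0: with only a
handful of sex-specific studies, likelihood trimming under this
deliberately small model proved unstable in simulation (it removes
informative contrasts as readily as contamination), so robustness is left
to the study random effect.

## Cascade: hierarchical meta-regression over the location tree

Each node of the global → super-region → region → country tree carries a
parameter vector $\theta = (v_1, \dots, v_K, b_{\mathrm{sex}},
b_{\mathrm{HAQI}})$: values of a piecewise-linear logit-coverage curve at
age knots $\{1, 5, 10, 15, 20, 30, 40, 50, 60, 70, 80, 100\}$, a fixed
female–male offset, and a per-unit HAQI coefficient (HAQI centred at
100). An estimate covering age band $[a_0, a_1)$ contributes through the
*band average* of the curve (exact trapezoid integration of the hat
basis), so wide bands are not treated as point observations.

The likelihood is Gaussian on observed logits with known delta-method
variances **plus** a between-study heterogeneity variance $\tau^2$,
estimated once at the global node by REML (using a saturated age-band
design so curve misfit does not inflate it) and then used as a
study-block covariance in every node: rows from one study are correlated,
so a country informed by a single large survey is treated as one unit of
evidence, not many.

Priors implement the cascade. The global node gets a vague prior plus a
first-difference smoothing prior across adjacent knots (SD 1 per step),
which also makes the curve extrapolate flatly below the youngest surveyed
ages. A child's prior is centred at its parent's fit, with the knot
values deviating through a *common level shift* (SD 0.8 / 0.5 / 0.3 at
super-region / region / country) plus small independent per-knot wiggles
(0.25 × the level SD). The level-shift-plus-wiggle structure matters:
band-averaged data constrain only averages of knot values, and a purely
diagonal prior would let interior knots see-saw around a correct band
mean. The sex offset deviates with 0.5 × the level SD and the HAQI
coefficient with 0.05 × (a per-unit-HAQI scale is an order of magnitude
smaller than a logit-level scale). These prior strengths are package
defaults exposed in `cascade_config()`; nothing in the source evidence
pins them.

Because the model is linear in $\theta$ with Gaussian likelihood and
prior, each node's posterior mode is a closed-form ridge solution — no
optimizer, and a node without data reproduces its parent *exactly*. Two
structural constraints are hard: coverage below age 1 is identically zero
(no parameter exists there), and the curve is non-increasing on [80, 100],
imposed by an exact one-constraint active set (if the unconstrained fit
rises, it is refit with $v_{100} = v_{80}$).

**Time.** Calendar time enters through the HAQI covariate and through the
data window: estimates inform fits within ±7 years of the prediction
years. `assign_data()` implements the per-year window; `run_cascade()`
fits each node once on data within the window of the whole prediction
range, which keeps "one fit per node" while still excluding stale data.
No free secular-trend term is included — a deliberate limitation that
mirrors the reliance on HAQI for time variation.

**Uncertainty.** Each node's parameter covariance is the inverse of the
penalized information matrix; 500 multivariate-normal draws per node
propagate through the inverse logit into coverage draws. A covariance
made singular by the active tail constraint is expected and floored at
$10^{-10}$; genuinely indefinite matrices trigger a warning.

## Aggregation

Coverage draws are multiplied cell-wise by prevalence draws (draw $d$
with draw $d$) into treated-case counts, summed over countries per draw
up the tree (the suite checks conservation exactly), and summarized as
the draw mean with a 95% uncertainty interval from the 2.5th/97.5th
percentiles (type-7 linear-interpolation quantiles, pinned for
bit-stability). Proportions are always formed **per draw** as
treated/cases and then summarized — never as ratios of summaries — and
both-sex results sum counts per draw rather than averaging proportions,
which preserves count conservation and reproduces the classic reversal
(Simpson's paradox) when fast-growing low-coverage strata drag an
aggregate down while every stratum improves. Age-sex standardised rates
weight stratum coverage by the global case distribution of the latest
reported year (configurable; the choice of reference year is not pinned
by the source evidence).

## The synthetic world

`generate_world()` / `generate_surveys()` create data with the structure
the analysis assumes, at the scale of the real evidence base (18
countries in a 3 × 2 × 3 tree, 32 studies, ≈150 estimates, ≈60–75 matched
pairs): true coverage is logit-linear in HAQI (slope 0.04) with a female
advantage of 0.35 logits and an age curve rising from 15 to a plateau at
40 with a mild decline after 80; indicator biases are 0.18 (antidepressant
use) and $0.06 - 0.012\,(H - 100)$ (any-service use); studies carry
Gaussian random effects (SD 0.3); proportions get binomial noise at
100–2000 cases; 85% of study-band cells are collapsed to both-sex rows;
5% of rows are shifted by ±1.5 logits with alternating sign (sign-balanced
so that trimming, not bias, is what contamination tests exercise). The
female share of cases is flat in age (≈0.60, jittered by country): MDD's
female excess is roughly constant across adult ages, and an age-varying
share would confound a sex model that deliberately has no age terms.

What the generator does *not* emulate: survey-instrument differences,
recall periods, non-representative sampling, within-country subnational
variation, or country-level deviations from the HAQI relationship.
Passing recovery tests therefore show that the pipeline recovers its own
generative structure under realistic noise — not that real-world MAT
estimates are unbiased.

## Numerical choices and degenerate inputs

* Proportions of exactly 0 or 1 are clamped to $1/(4n)$ and $1 - 1/(4n)$
  before the logit; a missing standard error falls back to the binomial
  $\sqrt{p(1-p)/n}$; rows with neither uncertainty nor sample size are
  rejected with reasons.
* HAQI values for missing years are interpolated linearly within a
  country's observed span and held constant outside it.
* Age intervals are half-open $[a_0, a_1)$; bands are clipped to
  $[1, 100]$ for integration.
* REML/ML profiles of $\tau^2$ are one-dimensional `optimize()` calls with
  an explicit comparison against the $\tau^2 = 0$ boundary.
* Backward-elimination BIC ties are broken by the larger p value;
  trimming iterations are capped at 100 with a warning on
  non-stabilisation.
* All randomness is seeded: the world from its config seed, survey
  generation from seed + 1000, node draws from the cascade seed plus a
  fixed multiple of the node index. Identical configurations produce
  byte-identical CSV output.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run, by design, at the scale of
the emulated study: 200 replicates for crosswalk and sex-model recovery,
50 (tests) or 20 (script) replicates of the 18-country world for cascade
recovery, and 500 draws for the full pipeline run. These sizes give
Monte-Carlo standard errors comfortably below the tolerances being
checked.

## Known limitations

* Under the default noise conditions (32 studies, study-effect SD 0.3, 5%
  contamination, 85% collapsed rows), replicate-level recovery of
  country logit surfaces plateaus around an RMSE of ≈0.3–0.4: the global
  level itself wanders by ≈0.1 across replicates, the sex offset inherits
  the sex model's sampling noise, and country fits track their own
  studies as strongly as the default priors allow. Materially tighter
  recovery would require more studies or weaker heterogeneity, not a
  different estimator.
* The sex model is deliberately minimal (intercept + proportion female);
  it relies on the female share of cases being unconfounded with study
  level. Its estimate is heavy-tailed in small evidence bases.
* Crosswalk corrections are not sex-specific, mirroring the sparsity of
  the underlying evidence.
* The cascade has no secular trend beyond HAQI and stops at the country
  level (no subnational nodes).
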