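# matcov

Estimation of the proportion of people with major depressive disorder
(MDD) who receive **minimally adequate treatment** (MAT) — by country,
age, sex, and year — from sparse, heterogeneous survey data.

Population surveys that measure treatment among people with MDD are rare,
and the ones that exist disagree on what they measure: some report MAT
(a month of pharmacotherapy plus physician follow-up, or ≥8 psychotherapy
visits), others report antidepressant use or any mental-health-service
use; most collapse the sexes; most countries have no survey at all.
`matcov` implements the full estimation chain that turns such an evidence
base into a coverage surface with uncertainty:

1. **Crosswalk** — a trimmed mixed-effects network meta-analysis on
   matched logit differences,
   `logit(p_alt) − logit(p_MAT) = β_AD·[AD] + (β_ANY + β_ANY×HAQI·(HAQI−100))·[ANY] + u_study + ε`,
   used to adjust proxy indicators to the MAT reference level. Trimming
   removes the 5% of pairs with the worst likelihood contributions;
   backward elimination prunes terms by BIC.
2. **Sex split** — a model `logit(p) = β₀ + β₁·φ` on the proportion of
   cases that are female (φ), solved in reverse by bisection so that the
   two sex-specific outputs reproduce each both-sex input exactly.
3. **Cascade** — a hierarchical meta-regression over the
   global → super-region → region → country tree: a piecewise-linear
   logit age curve (structural zero below age 1, non-increasing on
   80–100), a fixed sex offset, and a Healthcare Access and Quality Index
   (HAQI) covariate, with each parent fit acting as the Gaussian prior
   for its children and between-study heterogeneity as a study-block
   covariance.
4. **Aggregation** — 500 parameter draws per location are multiplied by
   MDD case-count draws into treated-case counts, summed up the
   hierarchy per draw, and reported as means with 95% uncertainty
   intervals (2.5th–97.5th percentiles), plus age-sex-standardised rates
   and percent change between years.

A synthetic-data generator (`generate_world()`, `generate_surveys()`)
reproduces the statistical structure of the real evidence base — ~32
studies, ~150 estimates, indicator biases, study random effects, both-sex
collapsing, 5% outlier contamination — so every stage is validated by
parameter recovery. See the methods vignette
(`vignettes/matcov-methods.Rmd`) for the models and their assumptions.

## Worked example

```r
library(matcov)

cfg       <- world_config(seed = 42)           # 18 countries, 2000-2021
world     <- generate_world(cfg)
estimates <- generate_surveys(world, cfg)      # 169 survey rows

pairs <- build_matched_pairs(estimates, world$haqi)   # 80 matched pairs
cw    <- fit_crosswalk(pairs)
round(cw$beta, 3)
#>       beta_ad      beta_any beta_any_haqi
#>         0.191        -0.057        -0.015
cw$n_trimmed
#> [1] 4                                      # = ceil(0.05 * 80)

adjusted <- apply_crosswalk(estimates, cw, world$haqi)
sexmod   <- fit_sex_model(adjusted, world$prevalence)
sexed    <- split_both_sex(adjusted, sexmod, world$prevalence)

fit <- run_cascade(sexed, world$hierarchy, world$haqi,
                   cascade_config(seed = 42))
cov <- coverage_draws(fit)
res <- build_results(cov, world$prevalence, world$hierarchy,
                     years = c(2000, 2021))
subset(res, location_id == "G" & sex == "both",
       c(year, proportion_mean, proportion_lower, proportion_upper,
         change_mean))
#>   year proportion_mean proportion_lower proportion_upper change_mean
#> 3 2000        10.37755           8.9850         11.69537          NA
#> 6 2021        12.13381          10.7689         13.59853    17.01784
```

Reading the output: the fitted crosswalk recovers this world's injected
antidepressant bias (0.191 vs a generative 0.18) and trims exactly 5% of
pairs; the final table says that in this synthetic world 10.4% (95% UI
9.0–11.7) of cases received MAT in 2000 and 12.1% (10.8–13.6) in 2021, a
+17% relative change computed per draw. `run_pipeline()` chains the same
steps behind one call and adds validation and a provenance manifest.

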