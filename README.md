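# dormantlink

Reactivating dormant randomised controlled trials by probabilistic linkage
to administrative school records.

## What this is for

A *dormant* trial is a completed randomised trial whose active follow-up
ended but whose retained participant identifiers (names, dates of birth,
postcode histories) still permit follow-up by record linkage. For trials
that randomised infants, national pupil registers hold mandatory exam
results at ages 11 and 16 — long-term cognitive endpoints collected
independently of the trial, with far lower attrition than conventional
follow-up. `dormantlink` is aimed at trial statisticians and
epidemiologists designing or auditing such reactivations. It provides,
end to end:

* **Synthetic data** (`simulate_register()`, `simulate_trials()`,
  `corrupt_identifiers()`): a national pupil register and seven infant
  formula trial cohorts (1763 children; preterm, term small-for-
  gestational-age and term populations) with ground-truth links, permuted-
  block randomisation within centre strata, twins, infant deaths, register
  absence, and a configurable identifier error model — so every stage is
  testable without confidential data.
* **Identifier preparation** (`standardise_name()`,
  `canonicalise_postcode()`, `build_identifier_chronology()`):
  canonical comparable identifiers and deduplicated, time-ordered
  histories.
* **Linkage** (`generate_candidates()`, `score_candidates()`,
  `select_best_links()`, `evaluate_linkage()`): blocked candidate
  generation (up to four per participant), Fellegi–Sunter agreement
  weighting, and greedy one-to-one selection constrained by trial-side
  knowledge of deaths and twins.
* **Outcomes** (`build_analysis_dataset()`, `standardise_internal()`,
  `standardise_external()`, `derive_binary_outcomes()`): within-trial and
  national-reference standardised exam scores, plus binary attainment
  indicators.
* **Inference** (`impute_chained()`, `fit_mean_difference()`,
  `fit_odds_ratio()`, `pool_rubin()`, `mdes()`,
  `run_sensitivity_matrix()`): intention-to-treat estimation with chained
  multiple imputation, HC1 sandwich-robust variance, Rubin pooling, a
  minimum-detectable-effect calculator, and a five-way sensitivity grid.
* **Orchestration** (`run_pipeline()`, `make_report()`): one seeded,
  byte-reproducible run from simulation to report, all artefacts plain
  CSV/JSON. A thin CLI wrapper ships in `inst/scripts/run_pipeline.R`.

## The model in brief

**Linkage.** A candidate pair's score is the log-likelihood ratio of its
field agreement pattern: for field *f* at agreement level *l* (exact,
partial, neighbouring authority, disagree, missing),

    w_{f,l} = log2( m_{f,l} / u_{f,l} ),    score = Σ_f w_{f, l(f)}

with `m` the level's probability among true matches and `u` among
non-matches. Links are accepted above a score threshold (default 0: match
likelier than non-match) under one-to-one greedy assignment; children who
died before school entry are never linked, and twin candidates are ceded
to the co-twin whose forename matches.

**Estimation.** For each trial, the primary analysis is OLS of the
within-trial standardised maths score at 16 on the arm indicator plus
pre-specified baseline covariates, with HC1 sandwich variance
`n/(n−k) (X'X)⁻¹ X' diag(e²) X (X'X)⁻¹`; missing covariates and outcomes
are imputed by chained equations (m = 15, predictive draws), and
estimates pool by Rubin's rules, `T = W + (1 + 1/m) B`, with normal
reference intervals. The minimum detectable effect at level α and power
1−β for analysable arm sizes n₁, n₂ is
`(z_{1−α/2} + z_{1−β}) √(1/n₁ + 1/n₂)`.

## Worked example

```r
library(dormantlink)

# published accounting: per-arm linked/randomised counts summed
acc <- trial_accounting()
sprintf("randomised %d, linked %d (%.1f%%)",
        acc$randomised_total, acc$linked_total, acc$link_pct)
#> "randomised 1763, linked 1607 (91.2%)"

# detectable standardised differences at the published linked sizes
mdes_table()
#>   trial_id  n1  n2      mdes
#> 1      NEP 108 114 0.3761976
#> 2   NETSGA 135 134 0.3416337
#> 3  LCPUFAP  82  89 0.4288446
#> 4  LCPUFAT 137 143 0.3349304
#> 5    IRONT 149 150 0.3240415
#> 6    PALMT  98  92 0.4066995
#> 7  NUCLEOT  90  86 0.4224640

# one seeded run of the iron-trial cohort under the null generator
cfg <- default_config(seed = 20211111, population_size = 2500)
cfg$trials <- "IRONT"
res <- run_pipeline(cfg, "runs/demo", quiet = TRUE)

res$flow
#>   trial_id      arm randomised excluded_death linked unlinked gcse_maths_available
#> 1    IRONT modified        162              0    153        9                  147
#> 2    IRONT standard        165              0    156        9                  144

subset(res$estimates, outcome == "sd_maths16")[,
  c("trial_id", "analysis", "estimate", "ci_low", "ci_high")]
#>   trial_id              analysis estimate ci_low ci_high
#> 1    IRONT           MI_adjusted  -0.0056  -0.24    0.23
#> 2    IRONT         MI_unadjusted  -0.0035  -0.24    0.23
#> 3    IRONT           CC_adjusted  -0.0187  -0.25    0.21
#> 4    IRONT         CC_unadjusted  -0.0045  -0.24    0.23
#> 5    IRONT external_standardised  -0.0068  -0.25    0.23

sprintf("linkage precision %.3f recall %.3f",
        res$linkage$precision, res$linkage$recall)
#> "linkage precision 0.997 recall 0.997"
```

Reading the output: 94% of the simulated cohort links to a pupil record
(the rest are register-absent or missed under the default identifier
noise); all five sensitivity analyses of the within-trial standardised
maths score agree closely around zero — as they must, since the generator
injected no arm effect — and every confidence interval spans 0, the
"no evidence of benefit" pattern the run report labels explicitly.
`runs/demo/report.txt` holds the full human-readable summary; every
intermediate artefact (register, candidates, links, analysis dataset,
estimates, power table) sits alongside it as CSV/JSON.

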