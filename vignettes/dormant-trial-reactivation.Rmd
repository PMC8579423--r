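---
title: "Reactivating dormant trials: linkage and inference methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactivating dormant trials: linkage and inference methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormantlink)
```

## The problem

A *dormant* randomised controlled trial is one whose active follow-up ended
long ago but whose participant identifiers (names, dates of birth, postcode
histories) were retained. When the participants are children, national
school records offer a route to long-term outcomes with very low attrition:
examinations at ages 11 and 16 are mandatory, centrally collated, and
independent of the trial. `dormantlink` implements the full analytical
chain for this design — probabilistic record linkage of trial participants
to a pupil register, derivation of standardised academic outcomes, and
intention-to-treat effect estimation — together with a synthetic-data
module that generates a register and seven infant formula trial cohorts
(two nutrient-enriched, two LCPUFA-supplemented, one high-iron follow-on,
one sn-2 palmitate, one nucleotide; 1763 children randomised 1993–2001 in
five English centres) so that every stage can be exercised and validated
without access to any confidential data.

## The synthetic cohorts and register

`simulate_register()` draws a national pupil population. Each pupil has an
identity (forename, surname, date of birth, postcode mapped to one of ~50
local authorities with an explicit neighbour graph) and a single latent
ability $a \sim N(0,1)$ that drives every outcome:

* **Grades at 16.** For each of eight subjects, a latent score
  $a + \varepsilon$, $\varepsilon \sim N(0, 0.5^2)$, is cut at year-specific
  thresholds calibrated so that the national grade distribution over the
  nine-point letter scale (A* down to G, plus unclassified) matches a
  configured reference; thresholds drift by 0.03 SD per year, emulating
  grade inflation, and the per-year national mean and SD of the 8-point
  score are carried alongside so external standardisation can correct for
  the drift.
* **Scores at 11.** $50 + 10(a + \varepsilon)$, truncated to 0–100.
* **Special educational needs.** Ever-flagged with probability
  $\mathrm{logit}^{-1}(-2.2 - 1.2a)$.

`simulate_trials()` draws each trial's participants from register pupils
born in that trial's recruitment window, so that the trial children *are*
register children with ground-truth links. Arms are assigned by permuted
blocks of randomly chosen even length (2, 4 or 6) within centre strata;
because the published per-arm totals are slightly unequal, trailing blocks
are trimmed by flipping allocations drawn from the final block of a
stratum, preserving the blocked structure elsewhere. Baseline covariates
follow parametric approximations to the published per-trial summaries:
truncated normals for birth weight (g), gestational age (weeks) and
maternal age (years) over the printed ranges, and Bernoulli draws at the
printed proportions for sex, maternal smoking and maternal degree. Exact
quantile matching is deliberately out of scope. Participant ability is
then recomputed as

$$a_i = -\delta_{\text{pop}} + \beta^\top x_i + \tau \cdot
\mathbf{1}[\text{modified formula}] + e_i, \qquad e_i \sim N(0, 0.95^2),$$

with a non-negative population deficit $\delta$ (0.8 SD for preterm
cohorts, 0.45 SD for term small-for-gestational-age, reproducing the
pattern of lower raw grades in those trials), small covariate effects in
SD units (sex −0.15, maternal smoking −0.2, maternal degree +0.5, 0.1 per
within-trial SD of birth weight and of gestational age), and the injected
arm effect $\tau$ (default 0, making the generator an exact null model).
$\tau$ is contracted in SD units of the *observed* exam score — the scale
on which the primary analysis estimates effects — so the generator
converts it to the ability scale using the realised within-trial outcome
SD (ability spread plus subject measurement noise); an injected 0.33 is
recovered by the analysis as 0.33, not attenuated by measurement noise.
The register exam records of the sampled pupils are regenerated from the
recomputed ability, so the deficit and any arm effect propagate into the
data the linkage later recovers.

Structures the generator emulates because the design depends on them:
twin pairs sharing date of birth, surname and postcode but not forename
(5% of preterm participants, 1% of term; the source trials do not print
these counts, so the fractions are declared, configurable defaults);
infant deaths (3% preterm, 1% term-SGA, 0.5% term) whose children never
enter the school system; register absence (5%, emulating private schooling
and emigration — again declared, not inferred); and an identifier error
model (`error_model()`) with name typos (5%), post-trial surname changes
(3%), systematic date-of-birth transcription errors (2%), unrecorded
residential moves (10%, mostly within the same or a neighbouring
authority) and per-contact missing fields (2%). The zero error model is
the identity, which gives the exact-recovery contract the linkage tests
rely on. The observation window ends with the 2016 exam summer, so the
youngest cohort (nucleotide trial, born 2000–2001) mostly has no grades at
16 — reproducing the suppressed-cell situation in the real accounting.

What the generator does **not** emulate: real postcode geography or a real
national lookup (the synthetic universe has ~1000 postcodes), the real
register's schema, real grade-inflation correction tables (the analytic
per-year scale stands in), non-random school-type sorting, and any
dependence of linkage errors on social background. Passing tests therefore
demonstrate internal validity of the pipeline — calibration, monotonicity,
exact recovery under clean identifiers — not performance against real
administrative noise.

## Identifier preparation

Names are upper-cased, transliterated to ASCII (diacritics stripped), and
stripped of punctuation; hyphens and apostrophes are deleted rather than
replaced by spaces, which maximises exact-match recall and leaves genuine
spelling differences to the partial comparator. Dates of birth are kept
verbatim — impossible values are a matter for the error model, not
imputation. Postcodes are normalised to outward + inward form and checked
against the lookup; unknown codes pass through flagged invalid.
`build_identifier_chronology()` sorts each participant's contacts by date
and collapses consecutive duplicates, so the history retains every
distinct identifier state (every postcode the trial ever recorded) in time
order.

## The linkage model

Candidate generation is deterministic and blocked, with three passes:
exact date of birth; canonical surname + postcode outward code; and birth
year + forename initial + local authority. A candidate pair's agreement
pattern is evaluated per field against the *best-aligning* entries of the
two identifier histories, on the levels exact / partial / neighbouring
authority (postcodes only) / disagree / missing, where partial means
normalised edit-distance similarity ≥ 0.8 for names and exactly one
differing component for dates of birth. At most four candidates per
participant are retained, by provisional agreement count.

Scoring is the classical likelihood-ratio weighting of probabilistic
record linkage: each field–level combination has a probability $m$ under
true matches and $u$ under non-matches, and contributes
$w = \log_2(m/u)$; a candidate's score is the sum over the four fields,
with missing fields contributing 0. The shipped defaults
(`default_match_weights()`) are configuration aligned with the synthetic
error model and identifier universe — no EM estimation is performed, and
the weights are overridable wherever they appear.

Selection is greedy one-to-one assignment by descending score. Two pieces
of auxiliary trial knowledge that the register side cannot hold are
enforced first: children recorded as having died before school entry are
excluded categorically, and within a twin group a candidate whose forename
disagrees is ceded to the co-twin holding a forename-exact candidate for
the same pupil, which eliminates cross-assignment of twins who share
surname, date of birth and postcode. The acceptance threshold defaults to
score 0 — link exactly when the match hypothesis is likelier than the
non-match hypothesis — and ties break deterministically (more exact-level
fields, then lowest pupil id). Whether the original linkage enforced
one-to-one assignment is not documented; it is enforced here and asserted
post hoc. Greedy processing is prefix-stable, so raising the threshold can
only truncate the low-score tail of the assignment: recall is exactly
non-increasing in the threshold, and the precision/recall sweep traces a
monotone trade-off curve.

## Outcomes

Letter grades map to the 8-point scale (A* = 8 … G = 1, unclassified 0)
used before the 2017 numeric reform, which is the scale the study cohorts
sat. The primary outcome is the mathematics score at 16 standardised
*within trial*: $z = (x - \bar x_{\text{trial}}) / s_{\text{trial}}$ with
the sample SD over linked, surviving participants of both arms pooled.
Whether the original analysis pooled arms or used the control arm only for
the reference distribution is not documented; pooled arms is the declared
choice here, since it is symmetric and the arm means then centre to zero
by construction. Standardisation happens before imputation, and imputation
then operates on the z scale. The external sensitivity scale replaces the
within-trial reference with the per-year national mean and SD. Binary
outcomes: five or more subjects at grade C or above *including both
mathematics and English*, and ever receiving special-educational-needs
support.

## Inference

**Imputation.** `impute_chained()` is multiple imputation by chained
equations, written directly against the package's data structures:
m = 15 chains by default, each initialised from random draws of observed
values and iterated 10 times over the incomplete variables in ascending
missingness order (covariates typically first, outcomes last). Continuous
variables use Bayesian linear regression — residual variance drawn from
its scaled inverse-chi-square posterior, coefficients from their normal
posterior, then *predictive draws*, never conditional means; binary
variables use logistic regression with approximate-posterior coefficient
draws and Bernoulli predictive draws, falling back to observed-prevalence
draws under separation or non-convergence. Children recorded as having
died are excluded before imputation and appear in no completed dataset.
With nothing missing, the m completed datasets are identical copies, so
every multiply-imputed analysis degenerates exactly to its complete-case
counterpart — a property the tests assert to 1e-10.

**Estimation.** Mean differences come from OLS of the standardised score
on the arm indicator, adjusted (by default) for the pre-specified baseline
covariates: maternal smoking, maternal education, infant sex, birth
weight, gestational age, and study centre. The variance is the HC1
heteroscedasticity-robust sandwich
$\frac{n}{n-k}(X^\top X)^{-1} X^\top \mathrm{diag}(e^2) X (X^\top X)^{-1}$
at the individual level — HC1 is the common default in the trial-analysis
software tradition this pipeline mirrors, and the choice is confirmed
against an independent implementation in the tests. Odds ratios come from
maximum-likelihood logistic fits with the analogous robust variance on the
log-odds scale; separation is flagged and reported non-estimable rather
than silently penalised. Rank-deficient designs (a single-centre trial's
centre dummy) drop collinear columns with a message.

**Pooling.** Rubin's rules with a normal reference: pooled estimate the
mean of the m estimates, total variance $T = W + (1 + 1/m)B$. The normal
(rather than t) reference matches the 1.96-style intervals conventional at
these m and n; with m = 15 and n ≈ 300 the difference is negligible.
No multiple-testing correction is applied across trials or outcomes,
mirroring per-trial reporting conventions; readers should weigh the seven
trials' results jointly.

**Power.** The minimum detectable effect at two-sided level $\alpha$ and
power $1-\beta$ for analysable arm sizes $n_1, n_2$ is
$(z_{1-\alpha/2} + z_{1-\beta})\sqrt{1/n_1 + 1/n_2}$ on the SD scale.
Applied to the published per-arm linked counts this reproduces the
detectable differences reported for four of the six GCSE-age trials
(0.32, 0.33, 0.41, 0.43 SD); for the two nutrient-enriched trials the
closed form over the printed linked counts gives 0.38 and 0.34 against
reported 0.37 and 0.33 — the analysable sample sizes behind those two
printed values were evidently slightly different and are not printed, so
the package reports what the closed form yields and does not chase the
two-decimal values.

**Sensitivity matrix.** `run_sensitivity_matrix()` reports five labelled
analyses per trial and outcome — multiply-imputed adjusted (primary),
multiply-imputed unadjusted, complete-case adjusted, complete-case
unadjusted, and externally standardised — and flags any trial-outcome
whose estimable cells span more than a configurable margin (default
0.2 SD).

## Numerical and reproducibility choices

All randomness descends from one integer seed, fanned out to stages by a
fixed affine rule (`child_seed()`), so regenerating a later stage never
perturbs an earlier one; identical config + seed reproduces every output
file byte for byte. Degenerate inputs fail loudly: constant scores within
a trial (degenerate scale), a single observed outcome class, variables
100% missing, and register pools too small for a trial's recruitment
window are all errors, not warnings. Score ties in linkage and ordering
ambiguities everywhere resolve by explicit deterministic keys.

The validation suite sizes are package choices balancing Monte-Carlo
error against runtime: registers of 1000–10 000 pupils, the full seven-
trial cohort at its published 1763 randomised children for linkage
checks, and 500 replicates of the complete single-trial pipeline (the
iron-trial configuration, 327 children) for the null-calibration and
power checks. At those sizes the binomial Monte-Carlo error on a 5%
rejection rate is about 1 percentage point.

## Known limitations

* m/u weights are fixed configuration; there is no EM or clerical-review
  loop, so transferring the defaults to data with a different error
  profile requires re-specifying them.
* The imputation model is fully parametric (linear/logistic) with no
  interactions; it is congenial with the analysis model here, which is
  exactly what the calibration tests verify, but real data may need richer
  imputation models.
* The synthetic register's identifier noise is independent across fields
  and participants; correlated, clustered errors (shared addresses,
  systematic transcription habits) would be harder for the linkage than
  anything tested here.
* External standardisation uses the generator's analytic national scale;
  with real data the reference moments must come from the register
  provider.
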