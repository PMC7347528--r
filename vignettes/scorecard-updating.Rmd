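---
title: "Validating and updating a points-based antenatal risk scorecard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and updating a points-based antenatal risk scorecard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoreupdate)
```

## The problem

Antenatal risk selection instruments such as the Rotterdam Reproductive Risk
Reduction (R4U) scorecard summarise a pregnant woman's medical, obstetric,
and non-medical (socioeconomic) risk factors as a cumulative points score.
Each of ~50 dichotomous *predictor* items carries an integer weight of 0–3
points; unweighted *awareness* items flag mediators and red flags without
scoring. The cumulative score (0–98 for the default inventory shipped with
this package) is compared with a cut-off — 16 points by default — to decide
whether a woman enters a high-risk care pathway.

When such an instrument is carried to a new population, two questions arise:

1. **Validation** — does the score still discriminate between pregnancies
   that will and will not end in the composite adverse outcome (preterm
   birth and/or a small-for-gestational-age infant), and are its implied
   risks calibrated?
2. **Updating** — can individual items be re-weighted using the new data
   while keeping the instrument's structure, without overfitting?

`scoreupdate` implements both on any cohort in its simple CSV dialect, and
ships a synthetic-cohort generator so the entire pipeline is reproducible
and testable without access to patient data.

## The updating procedure

The development half of a temporal split (earlier enrolments develop, later
ones validate) is used for updating; the validation half is never touched by
imputation or re-estimation.

**Step 1 — candidate screening and selection.** A *reference model*
regresses the outcome on the cumulative score,
$\operatorname{logit} P(Y=1) = \alpha + \beta_{\text{score}} S$.
For each eligible predictor $x_j$ a bivariate model adds the single item:
$\alpha + \beta_{\text{score}} S + \beta_j x_j$. The coefficient $\beta_j$
is the item's *additional* effect beyond the score; items with a pooled
Wald p-value below 0.20 become candidates. Second-trimester items are not
re-estimated, and prior-pregnancy items are screened within multiparous
women only. Candidates then enter a joint model
(score + all candidates) trimmed by backward elimination at p > 0.20.

**Step 2 — heuristic shrinkage.** Data-driven selection makes the retained
coefficients optimistic. They are deflated by

$$\hat s \;=\; \frac{\chi^2_{\text{model}} - (\mathrm{df} - 1)}{\chi^2_{\text{model}}},$$

where $\chi^2_{\text{model}}$ is the likelihood-ratio statistic of the final
model against the intercept-only model and df counts *every* degree of
freedom considered: all predictors screened in step 1 plus all covariates
fitted in the final model (the score and the selected items). The factor can
be zero or negative when the model's signal is small relative to the
freedom spent; additional points then collapse to zero with a warning.

**Step 3 — sign evaluation.** Every item entered the scorecard for a
positive association with the adverse outcome, so a negative multivariable
coefficient is counterintuitive, usually an artefact of predictor
correlation. Such items are dropped. Items negative in *both* the screening
and the multivariable fit are flagged `review_required`: in a clinical
revision these go to literature and expert review; an automated pipeline
can only drop and log them.

**Step 4 — rescaling to points.** Each retained, shrunken coefficient is
divided by the coefficient per single score point and rounded:
$\text{points}_j = \max\!\big(0,\ \text{round}(\hat s\,\beta_j /
\beta_{\text{ref}})\big)$. By default $\beta_{\text{ref}}$ is the score
coefficient of the final multivariable model (the denominator that makes the
ratio internally consistent); a flag switches to the univariate reference
coefficient. The points are *added* to the item's original weight — the
procedure estimates additional effects — with a `replace` mode behind a
flag. Rounding is to the nearest integer, floored at zero; `floor` is
available. Since the source methodology never states how fractional ratios
become integers, this was a free choice.

```{r update-example}
sc <- counterintuitive_scenario(seed = 1)
x <- generate_cohort(sc$definition, sc$config)
dev <- cohort_split(assign_temporal_split(x, 2/3), "development")
res <- run_update(dev, sc$definition)
res$model
res$scorecard
```

The scenario above plants seven informative items of which two have a
negative direct effect masked by strong positive correlation (latent
$\rho = 0.9$) with a stronger item — their association on top of the score
is positive, their multivariable coefficient negative. The updating run
recovers that structure: the two masked items are selected, then dropped at
the sign check, and the remaining five receive positive additional points.

## Missing predictor responses

Item responses are imputed with chained equations
(`mice_impute()`, default `m = 20` completed datasets, 10 sweeps per
chain). Each incomplete item is regressed on the other included items plus
the outcome; coefficients are drawn from the asymptotic posterior of the
fit and missing entries redrawn as Bernoulli. Items with an observed
incidence strictly below 2% of the full sample are excluded from the
model-based step — rare items make logistic imputation models unstable —
and completed by marginal draws at their observed prevalence, never
appearing as covariates. The same marginal fallback (with a warning) covers
items observed in one category only or separated fits. The cumulative score
is *not* an imputation covariate: it is a deterministic function of the
items. The iteration count (10) is our choice; the number of imputations
(20) follows the source methodology.

Downstream inference pools per-completion estimates with Rubin's rules
(`pool_estimates()`): total variance $W + (1 + 1/m)B$, Wald tests against a
t reference with Barnard–Rubin small-sample degrees of freedom when the
complete-data df are supplied. How the original analysis combined its 20
imputations is unstated; Rubin pooling is the field default.

## Validation metrics

* **Discrimination** — `compute_auc_ci()` computes the AUC as the
  normalized Mann–Whitney statistic from midranks; the confidence interval
  uses the DeLong placement variance by default, with a stratified
  percentile bootstrap as the alternative.
* **Calibration** — `calibration_assess()` fits
  outcome ~ logit(predicted): intercept 0 and slope 1 indicate agreement;
  the curve reports observed event proportions in deciles of predicted
  risk. Boundary probabilities are clipped at a configurable epsilon with a
  warning; constant predictions are a flagged error (the slope is
  undefined). We report observed *event* proportions on the y-axis, the
  standard calibration quantity.
* **Threshold metrics** — sensitivity and specificity at the high-risk
  cut-off, plus the odds ratio of high-risk classification versus outcome
  (Haldane–Anscombe 0.5 correction for zero cells, with a warning).
* **Descriptive comparison** — `table_one()` produces counts, group
  percentages, and Pearson chi-square p-values by outcome group.
  Percentage denominators are full group totals including missing rows,
  and the Missing level is by default a category of the test: these are
  the only conventions that reproduce the published descriptive table this
  package's fixtures are checked against. The no-missing-category variant
  stays available via `chisq_include_missing = FALSE`.

`run_pipeline()` chains everything: temporal split, complete-case domain
validation of the original score (a participant is complete iff every
first-trimester predictor is observed; unanswered second-trimester items
score 0 like unticked boxes), imputation and updating on the development
split, and re-validation of the updated score on the *identical*
validation participants, so the sensitivity comparison holds its
denominator fixed. A participant-id disjointness check guards against
leakage between the splits.

## The synthetic generator

`generate_cohort()` draws correlated binary items from a latent-Gaussian
threshold model: exchangeable latent correlation, optionally overridden for
named pairs, with item $j$ positive when its latent falls below
$\Phi^{-1}(\text{prevalence}_j)$. The outcome is Bernoulli with
$\operatorname{logit} p = \alpha + \beta_{\text{pt}} S + \sum_j \gamma_j x_j$;
the intercept can be solved so the realized outcome rate matches a target.
Missingness is injected afterwards at a participant-level rate, MCAR or
MAR-on-outcome (odds multiplier), and a temporal split is assigned in
enrolment (row) order.

The bundled `hp4all_like.yaml` scenario fixes the study conditions the
package emulates: 1752 pregnancies, a 16% composite outcome rate, 0.06
log-odds per score point, 7% of participants with at least one missing
predictor, a 2/3 development fraction, heterogeneous item prevalences
(about a dozen under 2%, drawn once from a log-normal recipe and frozen in
the file), exchangeable latent correlation 0.10, and seven planted extra
item effects of which two are masked-sign items. The prevalence recipe and
correlation were chosen once so the score distribution sits in the regime
the instrument was designed for (median 6, a few percent above the cut-off)
and not revisited. The development fraction is a free parameter: the source
study splits by a calendar date but never reports the resulting sizes.

Two caveats on interpretation. First, because the planted extra effects
also load on the cumulative score, the *observed* univariate coefficient
per score point in a generated development set exceeds the structural 0.06
(typically ~0.1); the generating value is recovered exactly when the
extras are absent, which is how the parameter-recovery test is configured.
Second, the generator emulates the statistical structure of a screening
cohort — it does not simulate gestational age, birth weight, enrolment
dates, cluster structure, or item wording, so passing tests demonstrate
correctness of the *methods*, not clinical properties of any real
instrument.

## Numerical and design choices

* **Cut-off convention**: high risk is score ≥ 16. The source material
  uses both "16 or higher" and "above 16"; we follow the methods wording
  and make the cut-off configurable.
* **Missing items at scoring time** score 0 by default (`missing_policy =
  "zero"`), matching how a partially completed paper card is summed;
  `require_complete` supports complete-case analyses.
* **Eligibility bookkeeping**: `df_considered` = eligible predictors
  screened + 1 (score) + selected items. The verbal counting rule, not any
  particular worked value, is normative — reported worked values elsewhere
  cannot be reconstructed from published counts.
* **Multiparous-only items** enter the joint model with nulliparous
  responses coded 0 (their prior-pregnancy characteristic does not apply);
  screening subsets to multiparous women.
* **Model chi-square under multiple imputation** is the mean of
  per-completion likelihood-ratio statistics, logged in provenance.
* **Degenerate fits**: separation in a screening fit flags the item
  non-estimable (never a candidate); non-convergence in the joint model
  drops the most extreme coefficient with a warning; `glm.fit` warm starts
  carry imputation chains efficiently.
* **Determinism**: every stochastic step is seeded; the same configuration
  and seed reproduce byte-identical artifacts.

## Problem sizes used by the test-suite

The suite checks oracle equivalences (all-pairs AUC up to n = 200,
brute-force elimination traces up to 4 candidates, closed-form shrinkage
and Rubin pooling), parameter recovery (100 cohorts of n = 50,000 at the
structural 0.06 per-point coefficient, 3-standard-error coverage ≥ 95%),
the nominal behaviour of the 0.20 screening threshold (2,000 null
replicates, candidate rate within 20% ± 3 points), the masked-sign scenario
(exactly five positively updated items), and byte-identical pipeline
reruns. These sizes are the package's own choices, balancing Monte-Carlo
error against suite runtime.

## Limitations

The pipeline drops counterintuitive items rather than escalating them to
expert review; it does not implement decision-curve analysis, care-pathway
logic, or continuous-variable imputation (all items are dichotomous by
design). Updated weights from one cohort inherit that cohort's selection
biases; as with any shrinkage-after-selection heuristic, the shrinkage
factor is a coarse correction, not a substitute for external validation.
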