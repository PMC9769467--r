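---
title: "Suppression-based anonymization of a clinical public use file and its statistical bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppression-based anonymization of a clinical public use file and its statistical bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufanon)
```

## The problem

Open patient-level datasets ("public use files", PUFs) from clinical
registries make cohort descriptions and feasibility checks available
without an access procedure, but every released record carries a
re-identification risk. `pufanon` implements a complete
suppression-based anonymization pipeline for a 15-variable COVID-19
cohort PUF drawn from three sub-cohorts — a cross-sectoral platform
(SUEP, in- and outpatients), a population-based platform (POP,
retrospectively documented survivors), and a high-resolution platform
(HAP, hospitalized patients only) — together with the evaluation
harness needed to quantify the statistical bias the anonymization
introduces. Because the underlying registry is not redistributable, the
package ships a seeded synthetic generator calibrated to the published
per-cohort category counts, so the whole pipeline is reproducible and
testable end to end.

## Variable triage

Every released variable is scored 1–3 on three axes: *replicability*
(would the value be observed again about the same person),
*availability* (how easily an attacker obtains it from external
sources), and *distinguishability* (how strongly it singles a person
out). A variable whose total exceeds 5 is a *key variable*
(quasi-identifier); with the packaged ratings these are age group,
gender, quarter and year of first diagnosis, and cohort. All other
variables are *sensitive*, except two that are implicitly protected
because they are perfectly correlated with protected information:
hospitalization (determined by the mild-phase flag — a mild, purely
ambulatory course is exactly a never-hospitalized one) and follow-up
availability (determined by whether the follow-up sub-variables are
applicable). The implicit set is an explicit override list, not an
inferred correlation: the correlation is a structural property of the
schema, not something estimated from data.

```{r}
triage()$key_variables
```

## Privacy models and the suppression engine

Records are released unchanged or withheld entirely; the engine never
generalizes values (the coarsening of age into groups, and dates into
quarters, is fixed upstream in the schema). Decisions are taken per
*equivalence class* — all records identical on every key variable, with
explicit missing labels participating as ordinary categories. A class
is released iff

* **k-anonymity** (`k = 11`): the class has at least `k` members, so
  every published record is indistinguishable from at least 10 others
  and the prosecutor-model re-identification risk is at most
  1/11 ≈ 9.09%; and
* **t-closeness** (`t = 0.5`): for every sensitive variable, the
  distance between the class's value distribution and the variable's
  distribution over the *full original dataset* is at most `t`, so
  class membership leaks little about sensitive values.

Two distances are implemented: total-variation (half-L1) for nominal
variables, and a normalized earth-mover distance (mean absolute
cumulative difference, scaled so that full separation of the extreme
categories is 1) for ordinal ones. The release boundary is inclusive
(distance exactly `t` is releasable). The reference distribution is the
full original input, not the released subset, because inference risk is
judged against the underlying population; both the distance choice and
the reference choice are declared package decisions — the standard
t-closeness formulations — since neither is uniquely determined by the
deployment they model.

Suppression operates on whole classes. Releasing a k-sized subset of a
failing class would need a selection rule with its own disclosure
implications; class-level decisions keep both guarantees trivially
auditable (the audit lists every class with its size, decision, worst
variable and distance).

### Continuous release

Registries accrue cases, so the PUF is republished as the data grow.
`incremental_release()` recomputes class decisions on the cumulative
dataset at each snapshot and unions the result with everything already
published: no record is ever retracted. Class sizes only grow, so the
k-guarantee cannot newly fail for a published class; but the t-closeness
*reference* drifts as data accrue, so a published class can drift out of
`t`. Such a class is *frozen* at its previously released membership,
flagged in the audit (`frozen_classes`, `frozen_released_ids`), and
never silently extended — retraction would break the continuous-release
contract, silent extension would break the guarantee. The freeze is the
one place where the cumulative release can exceed `t`, and it is always
reported.

## Re-identification risk

`reidentification_risks()` computes the prosecutor-model profile:
per-record risk 1/(class size); maximum = 1/(smallest class), minimum =
1/(largest class). The reported *average* is record-weighted (the mean
of per-record risks, equal to `n_classes / n_records`); a
class-weighted average is available behind the `average = "class"`
flag. A one-shot `k = 11` release provably caps the maximum at 9.09%.
On growing synthetic streams the average risk trends downward —
hiding in the crowd — but is not step-wise monotone: a newly released
minimum-size class can nudge the record-weighted average up even as
existing classes grow. The tests therefore assert the trend (the
average never exceeds its initial level and ends below it), not
per-step monotonicity.

## Bias evaluation

The harness mirrors a before/after utility study:

* `compare_distributions()`: Pearson chi-squared homogeneity test on the
  per-category counts of a variable in the original versus the released
  data (no continuity correction). By default the explicit
  missing/not-applicable categories are excluded and categories empty in
  both datasets are dropped; both choices change the degrees of freedom
  (retained categories − 1) and are togglable. The two samples overlap
  (the release is a subset), which the standard test ignores; the
  comparison is used descriptively, as in the study design it
  replicates, and results with expected cells below 5 are flagged.
* `case_fatality_rate()` / `cfr_bias_curve()`: deaths over known-status
  cases in the SUEP and HAP cohorts (POP contains survivors only, so it
  never contributes deaths), tracked along the growing stream together
  with the released-data value and their difference.
* `adjusted_or()` / `or_comparison_curve()`: maximum-likelihood logistic
  regression of a binary outcome condition on a binary exposure
  condition plus categorical covariate dummies (reference levels: age
  18–39, female), complete-case after excluding explicit missing labels,
  with 95% Wald intervals on the log-odds scale. Separation or
  non-convergence flags the estimate; flagged or failed sizes appear as
  gaps in the curves, not as numbers.
* `fraction_published_curve()`: released share per snapshot, overall and
  per cohort.

## The synthetic generator

`default_generator_config()` encodes the study conditions: 4,562 cases
split SUEP/POP/HAP ≈ 1,697/2,346/519, with per-cohort marginals for age
group, gender, joint quarter–year of diagnosis, and the collapsed WHO
Clinical Progression Scale severity taken from the published per-cohort
category counts bundled in `inst/extdata/reference_marginals.csv`.
Sampling order per record: cohort → quarter–year (joint marginal) →
diagnosis date uniform within the sampled quarter → demographics →
most severe phase → derived flags and hospitalization → intensive care
(conditional on hospitalization) → invasive ventilation (conditional on
intensive care) → patient status → follow-up block. Sampling the
quarter–year category first and the exact date within it keeps the
date–quarter consistency invariant while reproducing the configured
quarter marginals, which a single uniform recruitment window per cohort
could not.

Inpatient death follows a logistic model
`logit P(dead) = β0 + β1·[age > 59] + β2·[male]` with defaults
β1 = log 2.5, β2 = log 1.3, β0 = logit 0.045 — an age effect within the
range reported for comparable inpatient cohorts and a baseline placing
the synthetic SUEP+HAP case fatality near 8%. The model is configurable
(`effect_spec`), and because the fitted analysis model matches the
generating model, Wald interval coverage is testable (≥ 90/100 seeded
replicates at a true adjusted OR of 4.0, n = 10,000).

Structural rules hold with probability 1, not approximately: POP
contains no deaths and is fully followed up; HAP is 100% hospitalized;
mild phase ⇔ never hospitalized; follow-up sub-variables are `n/a`
exactly when no follow-up is available. Conditional rates (ICU given
hospitalization, ventilation given ICU, referral share, missingness
overlays) derive from the same published counts.

What the generator does *not* emulate: longitudinal trajectories,
site-level clustering, secular drift in severity, or any cross-variable
dependence beyond the rules above — all other variables are
conditionally independent given cohort. Passing tests therefore show the
pipeline's mechanics and guarantees, and qualitative bias behaviour, on
data with realistic marginals; they do not certify bias magnitudes for
any real registry.

One consequence worth stating: the *shape* of the fraction-published
curve is accrual-dependent. On the default stream the early cases are
dominated by the homogeneous POP cohort (few, large equivalence
classes), so the published fraction starts high (~96%) and declines
towards ~81% as later SUEP/HAP accrual spreads over many quarter–year
cells below `k` — the opposite shape to a registry that starts sparse
and heterogeneous. The tests assert only what the mechanism guarantees:
released-id sets are nested, and the incremental release publishes at
least as much as an independent per-snapshot run at every size.

## Numerical and reporting choices

* Distances and probabilities are exact rational arithmetic in double
  precision; the only tolerance used in guarantees is 1e-8 on
  probability normalization.
* Degenerate inputs fail loudly: risk on an empty dataset, CFR with no
  known-status record, chi-squared with fewer than two retained
  categories, regressions with single-level outcome or exposure.
* Percentages are displayed with one decimal in cohort tables and two
  decimals for risks; raw proportions are retained in all return values.
* Diagnosis-date ties in the growth ordering are broken by case id, and
  undated records sort last, so continuous-release simulations are
  deterministic.
* All randomness flows from one integer seed; the pipeline derives a
  sub-seed per stage name so stages can be rerun in isolation.

Problem sizes in the test suite (synthetic streams of 1,500–4,562
records with snapshot step 250–500, oracle instances of at most 200
records, coverage at 100 replicates of 10,000) were chosen so each
property is exercised at a scale where its failure modes can actually
occur — class drift, frozen classes, gap sizes in OR curves — while the
whole suite stays comfortably interactive.

## Known limitations

* Whole-class suppression is conservative; a deployment willing to
  define a within-class selection rule could publish more records.
* The chi-squared comparisons treat overlapping samples as independent.
* The record-weighted average risk is one of several defensible
  averaging conventions; both are computed, one is the default.
* The generator's independence assumptions make regression models other
  than the built-in outcome model exactly null; use `effect_spec` to
  encode any association to be studied.
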