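---
title: "Methods: estimating comorbidity burden in inpatient cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating comorbidity burden in inpatient cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbid)
```

## The problem and the pipeline

Inpatient cancer patients frequently carry chronic conditions besides the
index cancer. This package estimates that comorbidity burden from
admission-level hospital records in four stages: cohort filtering,
condition scoring, pattern clustering, and outcome association modelling.
Each stage is exposed as ordinary functions; `comorbidity_burden()` runs
them as one fit and returns a classed object with `print`, `summary`,
`coef` and `plot` methods.

## Cohort filtering

Admissions are collapsed to one row per patient; demographics come from the
first admission by date (conflicts warn and resolve to the first
admission), diagnoses are the deduplicated union of primary and secondary
ICD-10 codes, treatment flags are unioned, and cost is summed missing-aware
(a patient's total is missing if any admission cost is missing, so that
mean imputation happens once, at the patient level).

Exclusion rules run in a fixed order — cancer type, diagnosis-date window,
histology, single admission — and each excluded patient is counted exactly
once at the first failing rule, which makes the filter-report stage counts
exhaustive, mutually exclusive, and reproducible. The order itself is a
design choice (any order yields the same retained set; only the per-stage
counts differ). The diagnosis date is operationalised as the first
admission date, and the window is half-open `[2017-01-01, 2019-11-01)` by
default. The single-admission rule excludes patients with exactly one
admission: a lone admission gives no treatment trajectory to analyse. The
configured 90-day window parameter documents the follow-up interval
motivating the rule; with only one admission on record it has no further
bite.

## Condition roster, scoring and severity

The roster is the cancer-specific adaptation of the Charlson index: solid
tumors, leukemias and lymphomas are excluded (cancer is the index disease),
the remaining conditions are consolidated to 14, and hypertension is added
because of its high prevalence in inpatient cancer cohorts. Connective
tissue disease ships as an optional 16th condition, off by default, because
roster definitions in the field vary on whether it is retained after
consolidation.

ICD-10 codes are matched case- and dot-insensitively against the published
Quan et al. (2005) prefix lists, shipped as an overridable YAML data file.
Two severity hierarchies apply: mild vs moderate/severe liver disease and
diabetes vs diabetes with complications — when codes for both members are
present only the severe member is positive. Hypertension's prefix list is
the `I10`–`I15` block; a hypertensive heart/renal disease code such as
`I11.0` therefore also matches heart failure or renal disease. This is
clinically intended (such codes document both conditions); the map
validator only rejects *identical* prefixes claimed by two conditions.

The Charlson score is the weight sum over positive conditions, weights 1–6
as published; hypertension carries weight 0 by default because it sits
outside the Charlson index and participates only in prevalence and pattern
analyses (configurable). Severity grading uses the widespread convention
none = 0, mild = 1–2, moderate = 3–4, severe ≥ 5; the thresholds are a
parameter because other cutpoints circulate. Age adjustment of the score is
deliberately not applied.

Group comparisons use the pooled-variance two-sample t test for continuous
variables and the Pearson chi-square without continuity correction for
categorical ones, mirroring standard baseline-characteristics tables.
Zero-variance continuous variables and degenerate contingency tables are
reported as undefined with a diagnostic instead of erroring.

## Pattern clustering

The entities clustered are **conditions** (indicator columns), not
patients: the reported comorbidity patterns are condition groupings such as
hypertension–diabetes, and clustering columns is what produces them. A
patient-mode analysis can be run by transposing the indicator matrix, but
it is not the default.

Within each cancer-type stratum:

* Conditions observed in fewer than `min_count = 3` patients are dropped —
  near-empty columns carry no co-occurrence signal and would otherwise
  produce degenerate correlations.
* Columns are z-scored (a no-op for the Pearson correlation, kept to make
  the standardisation step explicit) and the dissimilarity is
  `d = 1 − r`, mapping co-occurrence (r → 1) to distance 0 and
  complementarity (r → −1) to distance 2. `sqrt(2(1 − r))` is available as
  an alternative transform. `1 − r` is not a metric; no triangle inequality
  is asserted anywhere.
* Agglomeration is written from scratch with the Lance–Williams
  recurrences (average linkage by default; complete and single available).
  Equal merge distances are broken by the lexicographically smallest pair
  of cluster labels, a cluster being labelled by its smallest original leaf
  index; this makes the merge sequence deterministic, which the
  reproducibility guarantees rely on. The tests cross-check the merge
  sequences against a brute-force oracle that recomputes inter-cluster
  distances from the original matrix at every step, and against
  `stats::hclust` on tie-free inputs.
* The default cut height is 0.9 on the `1 − r` scale: conditions join a
  group only when their average correlation is materially positive
  (r ≳ 0.1), while independent conditions (r ≈ 0, d ≈ 1) stay separate.
  A per-stratum cluster count can be supplied instead; no default claim is
  made that any particular count reproduces a published dendrogram, since
  the cut rule behind published cluster counts is generally unstated.
* Membership: a patient belongs to a cluster iff all of its conditions are
  positive (an `at_least` relaxation exists). Assignment is exclusive by
  default; a patient matching several clusters goes to the one with most
  matched conditions, ties to the earlier cluster.

## Association models

Treatments are recoded to two binary outcomes: conventional treatment
(any of surgery, chemotherapy, radiotherapy) and targeted therapy. Missing
costs are mean-imputed (the post-imputation mean equals the observed mean
exactly, which the tests assert as an identity); an observed-only mode is
available because published analyses are often ambiguous about which was
used.

Each cluster is compared with the reference group on the subset
members ∪ reference: logistic regression for binary outcomes and linear
regression for cost, with the cluster indicator as exposure. The reference
is patients with **no identified comorbidity at all** (count 0) within the
same stratum; an alternative `"no_cluster"` reference (patients outside
every cluster) is exposed, since both definitions appear in practice.

Two covariate presets ship because reported adjustment sets conflict in the
literature this design follows: `"full"` (age, sex, education, insurance,
marriage, cancer stage — the default) and `"core"` (age, sex, education,
residency, marriage). Covariates without variation in a subset are dropped
from that fit and recorded; aliased (collinear) columns are named in the
result.

For binary outcomes both the log-odds coefficient with Wald 95% CI and the
exponentiated OR are reported, clearly separated — association tables in
this literature sometimes print coefficients under an "OR" heading, so the
package refuses to conflate the two. Fits are flagged "not estimable"
(rendered `\` in the report table) when the outcome is constant in the
comparison set or the fit shows separation (|coefficient| > 10, SE > 50, or
a fitted-probabilities warning); flags, not errors, so one degenerate cell
never aborts a run. The minimum cluster size for fitting is 10. The glm
convergence tolerance is tightened to 1e-12 so that saturated fits agree
with closed-form quantities to numerical precision.

## The synthetic cohort generator

The generator is the package's stand-in for hospital extracts and defines
the study conditions under which the pipeline is validated.

What it emulates, with defaults chosen once:

* **Demographics / cancer mix** — age ~ Normal(62.42, 11.62²) truncated to
  [18, 100]; insured 94.68%, married 87.74%, urban 64.96%; cancer-type
  shares 37.03 / 12.22 / 12.47 / 17.08 / 21.20% (lung, colon, rectal,
  breast, gastric); stage shares 2.66 / 28.31 / 21.37 / 29.10 / 18.56%.
  Per-type female probabilities (0.38, 0.45, 0.42, 0.99, 0.33) were chosen
  so non-breast types are male-dominated while the overall female share is
  ≈ 50%. Education (primary/secondary/tertiary = 0.35/0.45/0.20) is a
  generator addition so the covariate presets are fittable; no published
  marginal was available to copy.
* **Condition prevalences** — the 15 per-condition marginals of a
  4,666-patient inpatient cancer cohort (hypertension 32.04%, mild liver
  22.42%, …, paralysis 0.04%).
* **Co-occurrence** — a shared latent Bernoulli factor per block: the
  factor fires with probability equal to the mean block prevalence, and
  each member condition is drawn with an elevated/depressed probability
  calibrated so the marginal is exact and the within-block pairwise
  correlation approaches the block's `rho`. Loadings are clipped to the
  feasible range — for very unequal or very low prevalences the attainable
  phi-correlation is capped, a property of binary variables rather than of
  the sampler — and the calibrated correlations are recorded in the
  `realized_rho` attribute. The four default blocks (hypertension–diabetes,
  CVD–PVD, mild liver–renal, CHF–COPD at ρ = 0.45) are the hierarchy-valid
  condition pairs the pattern analysis is expected to recover; a
  diabetes–diabetes-with-complications pair is deliberately not planted
  because the scoring hierarchy makes those two mutually exclusive at the
  profile level.
* **Cost** — log-normal with meanlog 10.915, sdlog 0.762, the moment match
  to a mean ≈ 73,552 and SD ≈ 65,288 RMB; planted cost shifts are additive
  on the RMB scale. 5% of patients have missing cost.
* **Treatment** — logistic assignment: conventional baseline logit 2.0;
  targeted baseline −1.5 plus +1.0 for stage IV (targeted therapy is
  predominantly a late-stage option); planted pattern shifts add to the
  logit of patients positive for all of a pattern's conditions. The default
  planted effects (conventional −1.38 for CHF+COPD, targeted −0.9 for
  CVD+PVD, cost +17,000 RMB for hypertension+diabetes) mirror the
  magnitude and direction of effects reported for such clusters.
* **Admissions** — 1 + Poisson(2) per patient, so roughly one patient in
  seven is a single-admission patient and the corresponding filter is
  exercised; each admission carries one exemplar ICD-10 code per active
  condition (e.g. `I10` for hypertension) as secondary diagnoses, the
  cancer's own code as primary diagnosis, and an even share of the
  patient's cost.

What it does **not** emulate: joint demographic × condition structure
(conditions are independent of age, sex and stage given cancer type),
longitudinal disease progression, admission-level clinical detail,
realistic ICD-10 code diversity (one exemplar code per condition), and the
dependence of the "any comorbidity" rate on the full joint distribution —
matching all 15 marginals under near-independence yields an overall
comorbidity rate of ≈ 70–72%, not the ≈ 76% a real cohort with its
particular dependence structure can show. Passing tests therefore
demonstrate correctness of the pipeline's arithmetic and its ability to
recover known planted structure, not fidelity of any particular published
cohort's joint distribution.

## Numerical choices and degenerate inputs

* Merge-distance ties: broken lexicographically (see above); comparisons
  use a 1e-12 slack so floating-point noise cannot flip an order.
* Distance validation: symmetry to 1e-10, non-negativity, zero diagonal;
  negative round-off at r ≈ 1 is clamped to 0.
* Zero-variance condition columns are a hard error in
  `correlation_distance()` — they indicate rare-condition filtering was
  skipped.
* Empty cohorts: `generate_cohort()` returns an empty table;
  `prevalence_table()` and `comorbidity_burden()` error, since every
  downstream quantity is undefined.
* Determinism: all generation is driven by the single spec seed;
  `run_pipeline()` writes timestamp-free artifacts whose md5s are
  byte-identical across reruns of the same config.

## Validation problem sizes

The test suite validates marginal reproduction at n = 10,000 (3 binomial
SEs), planted two-block recovery at n = 5,000 with ρ = 0.6 over 100 seeded
replicates (the pairwise prevalence there is 0.40, where ρ = 0.6 is
comfortably feasible for binary indicators), oracle merge equality for 4–6
leaves across all three linkages, the 2×2 logistic/odds-ratio identity on
1000 random tables, null CI coverage at n = 2,000 over 200 replicates, and
planted effect recovery (targeted −1.0 log-odds, cost +17,000 RMB) at
n = 3,000 over 100 replicates. These sizes give stable pass/fail behaviour
at the asserted thresholds while keeping a full run in well under a minute
per property.

## Known limitations

* Mapping fidelity to any specific hospital's coding practice is
  unknowable; only the count→percentage arithmetic, not the code lists
  themselves, can be validated against published tables.
* The latent-factor sampler cannot reach high within-block correlations for
  very low-prevalence conditions (feasibility cap of the phi coefficient);
  `realized_rho` makes the attainable value explicit.
* `1 − r` clustering of binary indicators inherits the prevalence
  sensitivity of the phi coefficient: two rare conditions can never appear
  strongly correlated, so rare-condition pairs are hard to detect as
  clusters at realistic sample sizes — one reason rare conditions are
  filtered out first.
* Wald CIs are used throughout; for clusters near the minimum size with
  rare outcomes, profile-likelihood intervals would be preferable but are
  not implemented.
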