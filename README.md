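# comorbid

Inpatient cancer patients typically carry chronic conditions alongside the
index cancer, and that comorbidity burden shapes treatment options, cost and
prognosis. `comorbid` implements a four-step pipeline for estimating this
burden from admission-level hospital (HIS/EHR) records of five common cancer
types (lung, colon, rectal, breast, gastric):

1. **Cohort extraction** — parse admission CSVs and apply inclusion/exclusion
   rules (cancer type, diagnosis-date window, histology exclusions, removal
   of single-admission patients), collapsing to one analysis row per patient
   with an auditable filter report.
2. **Comorbidity characterisation** — map ICD-10 diagnosis codes to the
   cancer-specific comorbidity roster (14 NCI Comorbidity Index conditions
   plus hypertension), compute the Charlson score
   `CCI = Σ_j w_j x_j` (weights `w_j ∈ {1,…,6}`, hypertension `w = 0`),
   grade severity (none / mild 1–2 / moderate 3–4 / severe ≥ 5), and build
   prevalence and group-comparison tables (pooled t tests, Pearson
   chi-square).
3. **Pattern discovery** — per cancer-type stratum, drop rare conditions,
   form the correlation distance `d(i,j) = 1 − r(i,j)` between condition
   indicator vectors, run bottom-up agglomerative hierarchical clustering
   (hand-written Lance–Williams recurrences; average, complete or single
   linkage; deterministic tie-breaking), cut the dendrogram and assign
   patients to condition clusters.
4. **Outcome associations** — recode treatments to binary outcomes
   (conventional = surgery/chemo/radiotherapy; targeted therapy separately),
   mean-impute missing cost, and compare each cluster against the
   no-comorbidity reference with covariate-adjusted logistic (log-odds,
   Wald 95% CI, OR) and linear (RMB difference) models.

Because real hospital extracts are not shareable, the package ships a
synthetic EHR generator (`cohort_spec()` / `generate_cohort()`) that
reproduces the marginal structure of such a cohort — demographics, stage
mix, per-condition prevalences, log-normal costs — and plants condition
co-occurrence blocks (hypertension–diabetes, CVD–PVD, mild liver–renal,
CHF–COPD) plus treatment/cost effects with known ground truth, so every
stage of the pipeline is testable end-to-end.

Intended users: health-services researchers and biostatisticians analysing
inpatient cancer cohorts, and anyone needing a reproducible comorbidity
scoring + pattern-clustering reference implementation.

## Worked example

```r
library(comorbid)

adm <- generate_cohort(cohort_spec(n_patients = 1000, seed = 42))
fit <- comorbidity_burden(adm)
print(fit)
#> Comorbidity burden analysis
#>   patients: 865 (of 1000 before filtering)
#>   with comorbidity: 606 (70.06%)
#>   comorbidity clusters: 17 across 5 cancer-type strata (average linkage)
#>   association models: 24 fits (21 estimable)

print(fit$prevalence)
#> <prevalence_table> N = 865, with comorbidity 606 (70.06%)
#>   comorbidity rate by cancer type:
#>     breast      80 /   116  (68.97%)
#>     colon       77 /   109  (70.64%)
#>     gastric    131 /   200  (65.50%)
#>     lung       248 /   342  (72.51%)
#>     rectal      70 /    98  (71.43%)
#>   most prevalent conditions:
#>     hypertension         277  (32.02%)
#>     mild_liver           193  (22.31%)
#>     renal                151  (17.46%)
#>     diabetes             124  (14.34%)
#>     mi                   120  (13.87%)

print(fit$strata$gastric$cluster_set)
#> <condition_cluster_set> 4 cluster(s), exclusive assignment
#>   chf+copd+peptic_ulcer                    n = 2
#>   pvd+cvd                                  n = 5
#>   mild_liver+renal                         n = 18
#>   diabetes+hypertension                    n = 9
#>   without identified cluster: 166
```

Reading the output: 135 of the 1000 simulated patients fall to the
inclusion rules (mostly single-admission patients); 70% of the remainder
have at least one comorbid condition, with hypertension the most prevalent
(32%). In the gastric stratum the clustering recovers the planted
condition pairs — mild liver–renal disease and hypertension–diabetes — and
`fit$associations` / `fit$table` then report each cluster's adjusted
log-odds for conventional and targeted treatment and the adjusted cost
difference in RMB against patients without comorbidity ("1.00(reference)"
rows; cells that cannot be estimated, e.g. an outcome constant in the
comparison set, print as `\`).

File-based runs with artifacts (filter report JSON, scored patients,
prevalence tables, Newick dendrograms, membership and association CSVs plus
a provenance manifest) go through `run_pipeline()`, or the thin CLI at
`inst/scripts/comorbid.R` (`simulate`, `run-all`).

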