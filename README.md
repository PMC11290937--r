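# survrule

Association-rule mining of five-year cancer survivability.

`survrule` is for clinical researchers who have a table of categorical
patient records — clinicopathologic findings, treatment modality, survival
length in months — and want to discover and *rank* which attribute values
are most strongly associated with dying within, or surviving beyond, five
years. It was built around oral-cancer cohorts (the default schema carries
16 attributes such as T/N/TNM stage, surgical margin, extranodal extension,
lymphovascular and perineural invasion, with an explicit `N/A` category for
pathology fields of non-surgical patients), but the schema is fully
configurable.

## The method

Each patient becomes a *transaction* of items `"attribute: category"` plus
exactly one outcome item, either *death within 5 years*
(survival ≤ 60 months) or *survival of more than 5 years* (> 60 months).
Frequent itemsets are mined with Apriori, and each antecedent itemset A is
paired with an outcome consequent B and scored from the 2×2 contingency
table (n₁₁, n₁₀, n₀₁, n₀₀; |A| = n₁₁+n₁₀, |B| = n₁₁+n₀₁, N patients):

| measure | formula | reading |
|---|---|---|
| support | n₁₁ / N | joint frequency |
| confidence | n₁₁ / \|A\| | P(B given A) |
| lift | N·n₁₁ / (\|A\|·\|B\|) | 1 = independence |
| cosine | n₁₁ / √(\|A\|·\|B\|) | null-invariant similarity |
| correlation (φ) | (N·n₁₁ − \|A\|·\|B\|) / √(\|A\|·\|B\|·(N−\|A\|)·(N−\|B\|)) | binary Pearson correlation |
| chi-square | Pearson statistic, uncorrected (= N·φ²) | significance vs χ²₍₁₎ |
| odds ratio | n₁₁·n₀₀ / (n₁₀·n₀₁), Haldane–Anscombe +0.5 on zero cells | with a 95% Woolf interval |

Redundant rules (a longer antecedent that does not beat a retained
sub-antecedent's confidence for the same consequent) are filtered, each
rule gets a χ²₍₁₎ p-value, and rules are ranked by confidence within each
outcome, ties broken by support then antecedent string. Grouped five-year
survival (proportion in the >60-month bin) and a Kaplan–Meier
product-limit estimator S(t) = ∏_{tᵢ≤t} (1 − dᵢ/nᵢ) cover the survival
side. A seedable synthetic-cohort generator with plantable
antecedent→death associations of known confidence makes the whole pipeline
testable without access to any real cohort.

## Worked example

```r
library(survrule)

cohort <- generate_cohort(
  planted = list(planted_rule("extranodal_extension", "Positive", 0.85)),
  n = 897, seed = 7)

res <- mine_survivability_rules(cohort)
death <- res$ranked[res$ranked$consequent == outcome_items()[["death"]], ]
format_rule_report(death)[1:5, c(1, 2, 4:7)]
#>  Rule                                               Antecedent (LHS) Support
#>     1                                 Extranodal extension: Positive   0.054
#>     2                               Comorbidities: Multiple diseases   0.051
#>     3                                           TNM stage: Stage IVb   0.037
#>     4                                 Tumor location: Floor of mouth   0.097
#>     5 Treatment modalities: Surgery and concurrent chemoradiotherapy   0.117
#>  Confidence  Lift Cosine
#>       0.857 1.333  0.267
#>       0.780 1.212  0.249
#>       0.733 1.140  0.205
#>       0.731 1.137  0.332
#>       0.705 1.096  0.358
```

The planted antecedent comes back on top: 85.7% of its carriers died
within five years (target confidence 0.85), against a cohort-wide death
rate of about 64%, hence lift 1.333 > 1. The remaining rows are
noise-level associations drawn from the default marginals, with
confidences near the baseline death rate.

```r
g <- bin_survival_lengths(cohort)
grouped_survival_rate(g)
#> five-year survival (grouped): 0.357
km <- km_estimate(cohort$survival_months, cohort$dead_within_followup)
survival_rate_at(km, 60)
#> five-year survival (KM at 60 months): 0.357
grouped_survival_rate(reference_survival_lengths())
#> reference cohort grouped rate: 0.351
```

With complete follow-up the grouped rate and the Kaplan–Meier curve at
60 months agree exactly; the shipped reference survival-length bins give
the 35.1% five-year rate of the cohort they summarise.

## Command line

```sh
survrule simulate --n 897 --seed 42 --out cohort.csv
survrule mine --input cohort.csv --min-support 0.05 --min-confidence 0.10 \
              --max-antecedent 1 --top 10 --alpha 0.05 --out report.csv
survrule km   --input cohort.csv --out km.csv
```

`report.csv` carries the publication-style columns (`Rule`,
`Antecedent (LHS)`, `Consequent (RHS)`, `Support`, `Confidence`, `Lift`,
`Cosine`, `Correlation coefficient`, `Chi-square`, `OR (95% CI)`); every
run writes a `*.params.json` sidecar logging its parameters and seed.

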