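---
title: "Mining and ranking five-year survivability rules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and ranking five-year survivability rules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survrule)
```

## The problem and the model

Five-year survival is the standard yardstick of cancer prognosis. Given a
cohort of patients described by categorical clinicopathologic and
treatment attributes plus a survival length in months, `survrule` asks:
which attribute values co-occur most strongly with death within five
years, and which with survival beyond it — and in what order?

The analysis is market-basket style association-rule mining rather than
regression. Each patient record is encoded as a transaction of items
`"attribute: category"`, with exactly one item per schema attribute plus
exactly one of two outcome items. The outcome dichotomy is
`survival_months > 60` for long-term survival: the 49–60-month bin of the
grouped survival distribution lies on the death side, so a patient
surviving exactly 60 months counts as a death within five years. The
non-available pathology category `N/A` (carried by patients who never had
surgery, hence no surgical-pathology findings) is a first-class item — it
is mined like any other category, never imputed and never dropped,
because "no pathology report" is itself strongly informative about
treatment path and prognosis.

Frequent itemsets are found by level-wise Apriori: a size-k candidate is
generated only from frequent (k−1)-sets and pruned unless every
(k−1)-subset is frequent (anti-monotonicity of support). Each frequent
antecedent itemset A free of outcome items is paired with an outcome item
B and scored from the 2×2 contingency table of indicator vectors:
support n₁₁/N, confidence n₁₁/|A|, lift N·n₁₁/(|A|·|B|), cosine
n₁₁/√(|A|·|B|), the φ correlation coefficient, the uncorrected Pearson
chi-square statistic, and the odds ratio with a 95% Woolf interval.

## Tunable parameters

* `min_support` (default **0.05**) and `min_confidence` (default
  **0.10**). Published clinical rule tables of this kind include rules
  with support below 0.09, so the defaults are deliberately permissive;
  raise them for larger attribute spaces. Both are proportions of the
  cohort.
* `max_len` (default **1**): maximum antecedent size. Clinical top-10
  tables conventionally rank single-factor antecedents; multi-item
  antecedents are fully supported by raising this, and the redundancy
  filter then becomes meaningful.
* `outcome_cutoff_months` (default **60**): the survivability dichotomy.
* `alpha` (default **0.05**): the per-rule chi-square significance level,
  one degree of freedom.
* `k` (default **10**): rows reported per consequent.

## Numerical and design choices

**Chi-square without continuity correction.** The Pearson statistic is
reported uncorrected so that the exact identity χ² = N·φ² holds on every
2×2 table; the test suite asserts it to 1e-9 relative tolerance on 1000
random tables. A Yates-corrected statistic would break the identity and
disagree with the φ column it sits next to.

**Degenerate tables.** Confidence requires |A| ≥ 1; a zero-support
antecedent is an error (such rules are never generated, since antecedents
come from mined itemsets). When a margin is degenerate (|A| or |B| equal
to 0 or N) φ and χ² are undefined and reported as `NA` rather than an
error. Lift and cosine are reported as 0 when n₁₁ = 0, the limiting
value, so rules at the "perfect negative association" end remain
representable.

**Odds ratio.** When any cell is zero, the Haldane–Anscombe correction
adds 0.5 to all four cells before both the point estimate and the Woolf
standard error √(Σ 1/cell); the interval is exp(log OR ± 1.96·SE). This
is the conventional choice when a rule table must print a finite OR for
sparse cells; no claim of optimality is made.

**Redundancy filter.** The filtering step is named but not defined in the
source methodology, so the package adopts the standard minimal-improvement
criterion: a rule is removed iff a retained rule with the same consequent
has a strictly smaller antecedent (subset) and at least equal confidence.
Confidence dominance is transitive along subset chains, which makes the
one-pass pairwise implementation idempotent (asserted in the tests). The
filter can be disabled (`filter = FALSE` / `--no-filter`).

**Ranking ties.** Reports must be reproducible, so ties in confidence are
broken by support (descending) and then by the canonical antecedent
string (ascending). The death consequent is listed first.

**Multiplicity.** P-values are raw per-rule chi-square tail
probabilities, matching how such tables are conventionally printed; an
optional Benjamini–Hochberg column (`bh = TRUE`) is off by default
because it changes the table's meaning from descriptive to inferential.

**Kaplan–Meier conventions.** The product-limit estimator uses
right-continuous step evaluation with events before censorings at tied
times — the convention of the `survival` package, against which the
estimator is tested to 1e-10 on random censored datasets. Grouped
five-year survival is a plain proportion (count in the >60-month bin over
cohort size), which equals the KM curve at 60 months whenever follow-up
is complete to 60 months; censoring support exists for the general path
only.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws each attribute independently from per-attribute
marginals. The shipped defaults mirror the marginal counts of a published
897-patient oral-cancer cohort (normalised to probabilities; two printed
rows do not sum to the cohort size and are used as printed). The age
marginal is the decade-bin integral of a normal model with the published
mean 64 and SD 8.88 years — the source reports no age histogram, so this
one-time choice is the conventional reporting model, not a fit.

Dependence enters only through *planted rules*: each names one antecedent
item and a target confidence, and a patient's death probability is the
confidence of the first matching planted rule, else the baseline
(default 582/897 ≈ 0.649, the reference cohort's death proportion).
Survival months are then uniform on 1–60 for deaths and 61–120 for
survivors, so the outcome dichotomy and vital status coincide by
construction; the exponential generator
(`generate_survival_times()`) exists separately for the Kaplan–Meier
path, where the closed form S(t) = exp(−λt) anchors Monte-Carlo checks.

What this does **not** emulate: the real cohort's joint dependence
structure (stage correlates with treatment, `N/A` pathology is determined
by surgery, attributes correlate with each other), covariate-dependent
censoring, or competing risks. A green planted-rule test therefore
establishes that the pipeline *recovers a known association of known
strength and ranks it correctly* — it does not establish that the
generator reproduces any real cohort, and no rule-level number from the
source study is asserted anywhere: the published top-rule table is not
internally consistent with its own marginal counts (e.g. its top
antecedent has a marginal frequency of 5.1%, which cannot yield the
printed support of 0.274), so it serves as a *format* target only.

## Known limitations

* Apriori is in-memory and unoptimised beyond candidate pruning; it is
  comfortable at clinical scale (hundreds of items, thousands of
  patients, antecedents of a few items) but is not a basket-data miner.
* Confidence ranking inherits confidence's blindness to the consequent
  base rate; lift, cosine and φ are reported alongside precisely so
  readers can see when a high-confidence rule is merely the base rate.
* No Cox regression, log-rank tests, or stage-stratified curves: the
  package scope is the rule-mining pipeline plus the two survival
  estimators it needs.
* Chi-square p-values are asymptotic; for very sparse rules the printed
  statistic is exact arithmetic but the implied test is approximate.
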