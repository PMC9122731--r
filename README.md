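# icdmine

Comorbidity and multimorbidity patterns — which diseases co-occur in the
same people — are usually studied one index condition at a time. Given a
longitudinal hospital discharge register (one row per coded diagnosis per
admission), `icdmine` instead mines the whole network of pairwise and
three-way disease associations with the Apriori frequent-itemset
algorithm, at the three-character ICD-10 category level. It is aimed at
epidemiologists and health-services researchers working with electronic
medical record (EMR) extracts.

## What it computes

Each patient's diagnoses are merged across all of their hospitalizations
into one binary *transaction* over ICD-10 categories (patients with a
single hospitalization are excluded, as are codes from chapters V--Z and
codes whose descriptions carry the catch-all word "other"). For a rule
A → B between disjoint itemsets of categories:

- **support** = P(A ∩ B), the joint prevalence of both itemsets in the
  cohort;
- **confidence** = P(A ∩ B) / P(A), the conditional probability of B given
  A — arithmetically the comorbidity of B with A;
- **lift** = P(A ∩ B) / (P(A) P(B)), symmetric in A and B; lift > 1 means
  positive dependence.

Frequent itemsets are mined level-wise with exact tid-set support counting
and downward-closure pruning; every ordered antecedent/consequent partition
is scored, filtered (default: support ≥ 0.001, confidence ≥ 60%, lift > 1,
antecedents of at most two categories, single-category consequents),
sorted by descending confidence, and split into cross-chapter versus
within-chapter associations.

Because real discharge registers cannot be shared, the package includes a
seedable synthetic cohort generator that plants association rules with
closed-form expected support/confidence/lift, so the whole pipeline is
testable end to end.

## Worked example

```r
library(icdmine)

cfg <- cohort_config(
  n_patients = 5000,
  planted_rules = list(
    planted_rule("G45", "I61", 0.08, 0.75, 0.02),
    planted_rule(c("E10", "N08"), "H36", 0.03, 0.85, 0.01)
  ),
  seed = 2026
)
fit <- mine_comorbidity_rules(generate_records(cfg), config = mining_config())
fit
#> <comorbidity_mining>
#>   5000 transactions over 20 items -> 254 frequent itemsets
#>   992 rules generated, 103 kept (103 cross-chapter, 0 within-chapter)
#>   top rules by confidence:
#> # A tibble: 5 × 7
#>      no antecedent consequent support confidence lift  partition
#>   <int> <chr>      <chr>      <chr>   <chr>      <chr> <chr>
#> 1     1 E10        N08        3.46%   100.00%    28.90 cross
#> 2     2 N08        E10        3.46%   100.00%    28.90 cross
#> 3     3 E10;H36    N08        2.92%   100.00%    28.90 cross
#> 4     4 H36;N08    E10        2.92%   100.00%    28.90 cross
#> 5     5 E10;I63    N08        0.66%   100.00%    28.90 cross
```

The planted transient-ischaemic-attack → intracerebral-haemorrhage rule is
recovered close to its design values (expected support 6%, confidence 75%,
lift 9.57):

```r
dplyr::filter(tidy(fit), antecedent == "G45", consequent == "I61")
#>   antecedent consequent support confidence lift
#> 1        G45        I61   0.059     0.7375 9.70

expected_metrics(planted_rule("G45", "I61", 0.08, 0.75, 0.02))
#>   support confidence  lift
#> 1    0.06       0.75  9.57
```

`tidy()` returns the full rule table, `glance()` the stage counts (raw
rows, excluded codes, dropped single-admission patients, transactions,
itemsets, rules), and `autoplot()` a support/confidence/lift overview.
File-based workflows go through `cmd_simulate()`, `cmd_mine()` and
`cmd_summarize()` (or the `inst/exec/icdmine.R` wrapper script), which
write CSV/JSON rule tables and a `manifest.json` recording the
configuration and every stage count.

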