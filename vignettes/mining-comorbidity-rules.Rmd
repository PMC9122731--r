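---
title: "Mining ICD-10 comorbidity rules from longitudinal hospital records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining ICD-10 comorbidity rules from longitudinal hospital records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdmine)
library(dplyr)
```

## The model

`icdmine` treats a hospital discharge register as a market-basket problem.
The unit of analysis is the *patient*, not the admission: all diagnoses a
patient ever received across their hospitalizations are merged into one
binary transaction over three-character ICD-10 categories. Mining at the
category level (letter + two digits, e.g. `I63`) trades clinical detail for
epidemiological stability — fourth-character subcategories are truncated
away on ingestion.

For a rule A → B between disjoint itemsets of categories,

$$\mathrm{support} = P(A \cap B), \qquad
  \mathrm{confidence} = \frac{P(A \cap B)}{P(A)}, \qquad
  \mathrm{lift} = \frac{P(A \cap B)}{P(A)\,P(B)},$$

with all probabilities estimated as exact fractions of transactions.
Support is the joint prevalence of the two itemsets, confidence the
comorbidity of B with A, and lift a symmetric dependence measure: a rule
and its reverse always share support and lift, and
$\mathrm{lift} = c_1 c_2 / s$ where $c_1, c_2$ are the two confidences and
$s$ the shared support. That identity is the basis of the package's
analytic validation of published rule tables (see
`lift_from_rule_pair()`): it lets a printed table be checked for internal
consistency without any access to the underlying data. Rules express
co-occurrence only; no causal or temporal ordering is implied or modelled.

## Cohort selection rules

Three filters precede mining, in this order:

1. **Single-hospitalization exclusion.** Patients with fewer than two
   distinct admission identifiers in the *raw* input are dropped.
   Admissions are counted before any code-level filtering: the criterion
   is about hospitalizations having happened, not about how many codes
   survive cleaning. A patient whose second admission carries only
   excluded codes is therefore retained (with the excluded codes removed).
2. **Code exclusion.** Codes from chapters V, W, X, Y (external causes)
   and Z (factors influencing health status) do not represent diseases and
   are removed, as are codes whose free-text description contains the word
   "other" — such codes lump heterogeneous conditions into one category
   and would produce uninterpretable rules. The token is matched as a
   standalone word, case-insensitively, so "Other gastritis" is excluded
   but "Motherhood-related myalgia" is not; substring matching would
   silently over-exclude. Both the chapter set and the token are
   configurable (`exclusion_policy()`). Chapter U is retained: the item
   universe runs A00–U99.
3. **Empty-transaction removal.** A patient whose every code was excluded
   would contribute an all-false row, which deflates every support without
   adding information; such patients are dropped and counted in the run
   manifest.

Malformed codes (first character not a letter, characters 2–3 not digits)
abort the run under `strict = TRUE`; the default lenient mode skips and
counts them, which is the faithful treatment of records with incomplete
data in registry extracts.

## The miner

Frequent itemsets are found level-wise (classic Apriori): singletons from
one scan, size-k candidates from joining frequent (k−1)-itemsets sharing a
(k−2)-prefix, with any candidate owning an infrequent subset pruned before
counting. Support counting uses per-item transaction-id sets and exact
integer intersection — no sampling, no approximation — so results are
reproducible to the byte and can be compared *exactly* against exhaustive
enumeration; the test suite does this on randomized databases of up to 12
items and 200 transactions. Itemsets are kept when support ≥ `min_support`
(inclusive), and all orderings are lexicographic (C locale) so identical
inputs give identical outputs.

Rule generation emits every ordered antecedent/consequent partition of
every frequent itemset of size ≥ 2. Sub-itemset supports are guaranteed by
downward closure and read from the mined table; if a caller supplies an
inconsistent table, the support is recomputed exactly from the database
when available, otherwise the inconsistency is an error rather than a
silent NA.

## Thresholds and their semantics

`mining_config()` defaults encode a deliberately asymmetric set of
comparisons:

| parameter | default | comparison |
|---|---|---|
| `min_support` | 0.001 | inclusive (≥) |
| `min_confidence` | 0.60 | inclusive (≥) |
| `min_lift` | 1 | **strict** (>) |
| `max_antecedent_size` | 2 | ≤ |
| `consequent_size` | 1 | == |

A rule at confidence exactly 60% is kept; a rule at lift exactly 1 —
exact independence — is dropped. The very low support floor keeps rare but
strongly associated patterns; the antecedent/consequent shape limits keep
rules interpretable and their subpopulations non-trivial. `max_len`
defaults to `max_antecedent_size + consequent_size` (3): no larger itemset
can contribute an admissible rule.

Kept rules are sorted by confidence descending — the highest-confidence
rules are the most clinically interesting — with ties broken by lift, then
support (both descending), then lexicographically; published tables only
state the primary key, so the tie-break order is this package's own
documented convention. Finally rules are partitioned by ICD-10 chapter
(first letter ≈ body system): *within-chapter* when every category in the
rule shares one chapter letter, else *cross-chapter*.

Expert review of mined rules (removing duplicates and clinically
intermediate items) is inherently manual; the package ships an optional,
clearly labelled heuristic approximation (`prune_redundant_rules()`,
dropping a rule whose proper sub-antecedent already achieves the same
consequent at no lower confidence), off by default.

Rendered tables print support and confidence as percentages with two
decimals and lift with two decimals (C `printf` rounding, i.e. half-even);
all stored values keep full double precision.

## The synthetic cohort generator

No real discharge register can be redistributed, so `cohort_config()` +
`generate_records()` emulate one at configurable scale:

- **Planted rules** with three probabilities each (`p_antecedent`,
  `p_conditional`, `p_background`) give closed-form expected metrics
  (`expected_metrics()`), making parameter recovery a quantitative test:
  at 50,000 patients the suite requires mined support and confidence
  within 3 binomial standard errors of their design values and lift within
  5% relative error, across 20 seeds. Rules draw independently per
  patient; rules sharing a category are OR-combined (and flagged), which
  keeps marginals tractable.
- **Noise items** are independent Bernoulli draws; the default prevalences
  (10 categories, 4%–30%, circulatory codes dominating) are shaped like
  the head of a tertiary-care diagnosis frequency distribution.
- **Admissions**: eligible patients draw `2 + Poisson(1.85)` admissions
  (mean ≈ 3.85 hospitalizations per patient, a realistic multi-year
  tertiary-care figure), and the patient's conditions are scattered across
  admissions uniformly at random. An admission that would otherwise be
  empty re-codes one of the patient's existing conditions — chronic
  conditions are re-coded at readmission in real EMRs, duplicates collapse
  in the binary encoding, and this guarantees the register shows the
  patient's true admission count.
- **Fallback diagnoses**: a patient whose draws produced no condition at
  all receives one code from a small disjoint fallback pool (every
  hospitalization has a codable principal diagnosis). This keeps all
  `n_patients` in the support denominator, so the planted closed forms are
  exact rather than conditioned on non-emptiness.
- **Adversarial content**: a configurable fraction of single-admission
  decoy patients, and per-admission injection of excluded codes (V–Z
  chapters, or "Other …" descriptions in chapters L/M/T, disjoint from the
  default item pools). The suite asserts none of it reaches the
  transaction database.
- Every emitted code carries a random fourth character (`"I63.4"`) to
  exercise truncation; generation is vectorised, driven by a single seed,
  and restores the global RNG state afterwards.

What the generator does *not* emulate: age/sex structure, calendar time,
admission ordering, coding error, and correlated disease clusters beyond
the planted rules. Passing recovery tests therefore demonstrates
correctness of the mining arithmetic and the selection rules, not clinical
validity of rules mined from any particular real register.

## Numerical and degenerate-input choices

- Support comparisons are exact double divisions of integer counts;
  thresholds stated as fractions of the same denominator (e.g. `3/11`)
  compare exactly.
- The empty itemset has support 1 by convention; an item absent from the
  universe is an error naming the item, not a zero.
- An input whose every patient is filtered out raises "no eligible
  transactions" rather than returning an empty database; downstream code
  can rely on `n_transactions ≥ 1`.
- Unreachable thresholds are *not* an error: the pipeline returns an empty
  rule table and a manifest recording zero kept rules.
- The run manifest cross-checks its own stage counts (kept ≤ generated,
  transactions ≤ patients, ingested ≤ raw) and fails loudly on internal
  inconsistency.

## Problem sizes used in the shipped checks

The bundled validation runs at desk scale by design: oracle-equivalence on
randomized databases of ≤ 12 items × ≤ 200 transactions (100 replicates),
an 11-patient hand-counted worked sample, and parameter recovery at
50,000 synthetic patients × 20 seeds with mining restricted to
`min_support = 0.05` (far below the planted support of 0.24, far above the
noise floor). Full-register mining at `min_support = 0.001` over a
thousand-category universe is the same code path; only the candidate
space grows.

## Known limitations

- Apriori is exact but exhaustive; for very low support floors over large
  item universes, FP-growth-style miners would be faster. Exactness and
  auditability were chosen over speed.
- Rule counts are threshold-sensitive; published rule sets additionally
  reflect manual expert curation that no algorithmic filter reproduces.
- Confidence is asymmetric and lift symmetric: neither establishes
  direction or causation, and the package deliberately offers no
  significance testing — with hundreds of thousands of candidate rules,
  naive p-values would be meaningless without a multiplicity model, which
  is out of scope.
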