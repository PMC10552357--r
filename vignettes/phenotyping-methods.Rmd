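---
title: "Methods: EMR phenotyping with interpretable case definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMR phenotyping with interpretable case definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenoforge)
```

This vignette is the package's own account of its methods: the rule model
and its assumptions, the learning procedure, what the synthetic generator
does and does not emulate, the numerical choices, and the design
decisions taken where the design was genuinely open.

## The rule model

A *case definition* is an OR-combination of clauses; a clause is
"at least `min_count` matching records within a rolling window, in a set
of source tables". Matching is by code prefix on the normalized code
(dots and whitespace stripped, upper-cased, so ICD-9 "627.2" and "6272"
both match the prefix "627", and ATC matching is case-insensitive) or by
membership of a unigram/bigram in a record's negation-filtered free-text.

Two modelling commitments follow from this form:

* **Windows are rolling day counts.** "Within 12 / 24 consecutive
  months" is implemented as 365 / 730 days between the earliest and
  latest of some `min_count` matching records. Calendar-month arithmetic
  is ambiguous (month lengths vary, and "consecutive months" does not
  say where the window anchors); the rolling form is unambiguous,
  order-free, and — decisive for a screening rule — *monotone*: adding
  records to a chart can turn a non-case verdict into a case verdict but
  never the reverse. The test suite checks the rolling evaluation against
  a brute-force search over all record subsets.
* **"Sub-codes" are prefixes.** A clause on "627" covers 627.1, 627.2,
  etc.; a clause on "G03CA" covers G03CA03. No dictionary is consulted:
  prefix syntax is exactly what "or any sub-codes" denotes in both coding
  systems.

## Free-text handling

Record free-text is short (≤ 255 characters; the source schema has no
physician notes, which is why no long-text NLP is attempted). Text is
lower-cased and split on punctuation, with a question mark kept attached
to its preceding token because an attached "?" is one of the uncertainty
cues. Features are all unigrams plus adjacent ordered bigrams within one
record — never across records, since records are independent short
strings.

Negation filtering precedes n-gram extraction. The package ships a
50-template lexicon (`inst/extdata/negation_lexicon.txt`) of negated and
uncertain constructions with a `{term}` slot — "not {term}", "{term}?",
"rule out {term}", "no evidence of {term}", "query {term}", … — applied
to a configurable set of target-term patterns (by default the
"menopaus\*" family and "climacteric"). Only the full 3-exemplar seed of
such lexicons is ever published, so the remaining 47 templates are the
package's own curation and are deliberately configuration, not code: a
deployment for another phenotype supplies its own file. A matched
template deletes the *mention* (the target token), not the record:
"not menopause; hot flashes" still contributes "hot" and "flashes".

## Feature engineering

Each base feature (code prefix or n-gram) is expanded into four binary
temporal variants: ≥ 1 instance anywhere, ≥ 2 within 12 months, ≥ 2
within 24 months, ≥ 2 anywhere. ICD-9 prefixes are generated at every
depth from 3 characters; ATC prefixes at the classification's level
boundaries (3, 4, 5, 7). Generating every depth rather than a curated
grouping is the permissive reading of "or any sub-codes" — the published
feature lists show prefixes at several depths — and costs only columns,
which the support filter and prescreen remove again.

Minimum support counts *patients*, not records: a feature must appear in
at least 10 patients' charts to be retained. On a default 2,776-patient
synthetic cohort, the pre-filter feature space is in the tens of
thousands (the suite asserts the 10⁴–10⁵ range).

The prescreen score is the ad hoc importance `(TP − FP) / P`: cases with
the feature minus non-cases with it, over the number of cases. It is
invariant under duplicating the cohort and ranks a perfectly
case-specific feature at 1. The top 300 features enter the learner.
**Leakage stance:** the prescreen is recomputed inside each outer
training fold, never on test or validation patients. The alternative —
prescreening once on the full train/test set — is a common reading of
such pipelines, but it lets test-fold labels influence the candidate
feature set; the per-fold variant is the conservative choice and is the
default (`top_k` in `learner_config`).

## Learning and model selection

The learner is CaRT (via `rpart`), chosen because root-to-leaf paths are
themselves readable rules — the entire point of the exercise is a rule a
human can audit, which excludes forests, boosting, SVMs and neural
networks. The optimisation metric everywhere is the F1-score,
F1 = 2(1/Sn + 1/PPV)⁻¹, which weighs false negatives and false positives
symmetrically and ignores true negatives; `f1_score(0, x)` is defined as
0, the continuous limit.

Nested cross-validation: 10 stratified outer folds estimate performance;
within each outer training fold, 10 stratified inner folds select the
hyperparameter set (branching criterion, maximum depth, minimum samples
per branch, class weights) with the highest mean inner F1. Fourteen
combinations of resampling (none / random over / random under /
combined) × reduction (RFE / kBF) × order are evaluated; the two orders
coincide when no resampling is done, which is what collapses 16 to 14.

Design choices inside this loop, each genuinely open:

* **Reduction/resampling placement.** Per combination and outer fold,
  reduction and resampling are applied once to the outer-training set in
  the configured order, and the inner hyperparameter search runs on that
  processed set. Re-running RFE inside every inner fold would multiply
  cost roughly tenfold and can only change which hyperparameters are
  picked, not the outer metrics' unbiasedness (outer test folds are
  never touched by either operation — asserted in code).
* **"Combined" resampling** meets at the rounded geometric mean of the
  class sizes: over-sampling the minority and under-sampling the
  majority move symmetrically on a log scale.
* **RFE** refits the tree and drops the lowest-importance half of the
  remaining columns per iteration (`rfe_step = 0.5`) down to
  `target_count = 30`; **kBF** keeps the 30 columns with the highest
  chi-squared association (the observed per-class feature totals against
  class-prior expectations — the convention of k-best selectors on
  binary features). Ties anywhere break lexicographically by feature
  name, making every selection reproducible.
* **Selection metric.** "Highest average validation metrics" is
  operationalized as highest mean outer-fold F1, ties broken by mean
  sensitivity then mean PPV — F1 is already the pipeline's objective, so
  letting it arbitrate is the only self-consistent choice.
* **Class weights** map to `rpart` case weights; "balanced" weights
  inversely to class frequency. `rpart` has no analogue of a randomized
  branching strategy, so the strategy field accepts only "best".
* **Importances** are normalized sums of primary-split impurity
  improvements (no surrogate credit), the convention under which a
  depth-1 tree on a perfectly separating feature scores exactly 1.0 for
  it. They sum to 1 within 1e-9 by construction.

## Simplification and validation

The winning combination trains one tree on the full train/test half. Its
top-9 nonzero-importance features are translated back into clauses
(every matrix column is, by construction, re-evaluable as a clause — an
equivalence the tests assert), and 9 singleton + 36 pairwise candidates
are scored on the train/test half through the rule engine. Pairs combine
with OR, not AND, because the rule model is a disjunction and OR
preserves monotonicity. Ties prefer higher sensitivity, then PPV, then
*fewer clauses* (simplicity), then name. The chosen definition is then
applied once to the held-out validation half — patients whose ids never
entered any training stage, which an explicit audit enforces — and
reported with binomial CIs.

CIs default to Wald (the same approximation behind the sample-size
formula), clipped to [0, 1]; Wilson and Clopper–Pearson are selectable
because published interval styles vary and are rarely named.
Zero-denominator metrics are reported as undefined (`NA`), never 0: a
silent 0 would masquerade as evidence.

## The synthetic generator

`generate_cohort()` emulates the *structure* of a primary-care
sentinel-network extract, not its marginal distributions: five source
tables, women aged 45–60 (uniform), a 10-year date span, ~19% case
prevalence, per-patient background record counts drawn negative-binomial
(mean 15, dispersion 1.5 — overdispersed, as chart volumes are), chronic-
condition distractor codes from the 11 validated ICD-9 families,
pseudo-clinical background vocabulary sampled Zipf-like (size 2,000) so
common words recur and the bigram space is large.

Cases are constructed to satisfy the planted definition — an ICD-9 627\*
pair within 24 months (30–700 days apart), a G03CA\* prescription, or
both, with affirmative menopause text in half of them. Non-cases carry
the noise that makes the problem non-trivial:

* **Sub-threshold signal** (10%): a single 627\* code, or a pair more
  than 24 months apart — the reviewer stance that one code alone is not
  diagnostic, and the reason the ≥2-within-24-months variant is strictly
  cleaner than its whole-chart sibling.
* **Negated text** (30%): a lexicon construction instantiated with a
  target term, which must never fire a text clause post-filtering (a
  tested invariant).
* **Isolated affirmative mentions** (10%): one stray target term, making
  text features noisy while code features stay clean.
* **Non-CA G03 prescriptions** (5% of all patients): hormonal
  contraceptives and synthetic-estrogen codes that make the coarser G03
  and G03C prefixes strictly noisier than G03CA. Without these (and the
  distant 627 pairs) the planted clauses would be extensionally
  identical to coarser variants and recovery of the *exact* clauses
  would be a tie-break accident rather than a property.

Reviewers flip each true label independently at rate 0.025 — calibrated
so the panel's expected Fleiss kappa is ≈ 0.84, the good-to-excellent
agreement reported for trained chart-review panels — and a 1/2,776
fraction of charts is marked unclassifiable and excluded downstream.
Majority-of-five consensus at this error rate mislabels ~0.1% of charts,
so consensus labels are near-truth; the generator is therefore a test of
the *pipeline*, not of robustness to reference-standard error.

What passing tests consequently do **not** show about real data: real
extracts have correlated comorbidity patterns, provincial coding
dialects, drifting completeness over years, informative missingness and
genuinely ambiguous charts. The generator makes no attempt at any of
these (a non-goal); results on it calibrate correctness of the
machinery, not expected field performance.

## Numerical and reproducibility choices

* Problem sizes: the stochastic recovery experiment runs ten seeds at
  n = 2,776 and prevalence 0.19 with the package's `reduced_grid()`
  (gini, depths {3, 5}, min bucket 5, class weights {none, balanced}) —
  the full `default_grid()` (192 sets) is for real analyses. Unit tests
  run at n = 60–500.
* All randomness descends from one run seed through named substreams
  (`split`, `nested_cv`, `final_tree`), so a config and seed reproduce a
  run exactly; cohort generation is byte-identical per seed.
* The sample-size formula returns the ceiling (a sample size is a count
  you must reach); its (0.80, 0.10, 0.19) evaluation is 1294.01 → 1295.
* Degenerate inputs: constant labels yield a single-leaf tree with no
  rules; empty charts satisfy no clause; an inner fold collapsing to one
  class skips that evaluation with a warning; a planted definition whose
  window cannot fit the configured date span is rejected at config time.

## Known limitations

* Clause windows support only the 12/24-month/whole-chart grid the
  feature variants use; arbitrary windows would need new variants.
* kBF's score and k-schedule follow the common chi-squared convention;
  other univariate scores are not implemented.
* The CLI surface is R functions plus `scripts/acceptance.R`; there is
  no shell binary.
* No ICD-10, no dictionary validation of codes beyond prefix syntax, no
  stemming beyond lower-casing, no laboratory or physical-exam features.
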