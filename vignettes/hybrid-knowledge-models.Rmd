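---
title: "Hybrid expert/learned knowledge models for heart-failure diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid expert/learned knowledge models for heart-failure diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcdss)
```

## The problem

Heart failure (HF) is a clinical syndrome, not a single measurement: the
diagnosis requires symptoms or signs of congestion *plus* objective
evidence of cardiac dysfunction, and the phenotype is then stratified by
left ventricular ejection fraction (LVEF) into HFrEF (LVEF < 40%),
HFmrEF (40% ≤ LVEF < 50%) and HFpEF (LVEF ≥ 50%).  A guideline-style
decision tree authored by experts is transparent and auditable, but in
practice it fails on exactly the records real clinics produce: ones
where an attribute the tree wants to test was never measured.  A tree
induced from data handles missing values natively but does not encode
the clinical definition and is harder to defend to a physician.

`hfcdss` implements a hybrid of the two: an expert clinical knowledge
model (CKM) is executed as-is wherever it can decide, and a learned
prediction model (PM) is *grafted* onto the CKM at the precise points
where records fall through — chiefly "Not Available" paths for Missing
attributes.  The refined model (R-CKM) keeps every expert decision
(expert precedence), covers more records, and remains a white-box: every
diagnosis comes with a root-to-leaf explanation trace, and the whole
model flattens into mutually exclusive IF–THEN production rules for a
shareable rule base.

## The knowledge-model container

A model is a single-rooted attribute-test tree over a fixed schema of 14
clinical attributes (demographics, symptoms/signs, history, physical
exam, ECG, NT-proBNP, and seven echocardiographic indices).  Branches of
an internal node partition the tested attribute's domain — half-open
intervals `[lo, hi)` for continuous attributes, `FALSE`/`TRUE` for
binary — so exactly one branch matches any present value.  Missing is a
first-class value, never imputed: a node may route it to one of its
branches (`na_route`, what the learner records) or down a dedicated
subtree (`na_branch`, what grafting adds), or have no Missing path at
all, in which case traversal stops and the record is *Uncovered*.  Every
node carries provenance (`expert`, `learned`, `grafted`), so the origin
of any decision is inspectable after hybridization.

The uniform `[lo, hi)` interval convention means every continuous
criterion is a "≥ threshold" test; the left-atrial-volume criterion is
therefore encoded as LAVI ≥ 34 mL/m² (guidelines phrase it as > 34, a
measure-zero distinction on continuous data).

## The expert model

`default_hf_ckm()` encodes the HF definition: no symptoms/signs → no HF,
regardless of imaging (asymptomatic dysfunction is not HF under the
definition); symptomatic records are stratified by LVEF; reduced LVEF
alone establishes HFrEF; mid-range and preserved LVEF additionally need
one supporting-evidence criterion.  The defaults
(`hf_thresholds()`) follow the 2016 ESC guideline's spirit on the
attributes the schema captures:

| criterion | default | units |
|---|---|---|
| NT-proBNP | ≥ 125 | pg/L |
| LAVI | ≥ 34 | mL/m² |
| LVMI | ≥ 115 (male) / ≥ 95 (female) | mg/m² |
| E/e′ | ≥ 13 | — |
| ECG | abnormal | — |

All five are configurable; published accounts of the method name the
criterion *categories* (congestion, systolic dysfunction, structural
disease) but not numeric cut-offs, so these defaults are a documented
operationalization, not a claim about the original system.  The expert
model deliberately ships with **no** Missing paths: supplying them is
the hybridizer's job, which keeps the division of labor honest and
testable.

```{r}
ckm <- default_hf_ckm()
diagnose(ckm, list(hf_symptoms_signs = TRUE, lvef = 27.1))
```

## The learner

`induce_cart()` is a CART-style recursive partitioner written for this
package: Gini impurity `1 - sum(p_k^2)`, candidate thresholds at
midpoints between consecutive distinct observed values, binary splits on
`FALSE`/`TRUE`.  Missing values at a candidate split are routed to the
side holding the majority of present records (ties to the low side), and
the chosen side is stored on the node as an explicit `na_route`, so
induced trees reach a leaf for every record; no surrogate splits.  Ties
between splits break deterministically: larger impurity decrease, then
earlier schema attribute, then smaller threshold.  Stopping rules:
pure node, `max_depth` (default 6, root at 0), `min_samples_leaf`
(default 5, counted after Missing routing), `min_impurity_decrease`
(default 0; a split must always decrease impurity strictly).  Leaf
labels are majority class, ties resolved in the fixed label order
HFrEF, HFmrEF, HFpEF, NoHF.

Only the CART-style learner is implemented natively — it is the
algorithm the final system uses.  Competing learners enter through
`rank_algorithms()`, which scores candidates on min-max-normalized
held-out accuracy (weight 0.6) against rule count and attribute count
(0.2 each, fewer is better, since compact rule bases are easier to
audit); the exact weighting in the method's original lineage is not
published, so the weighted min-max form here is the package's own
documented surrogate with configurable weights.  Accuracy for a
candidate comes from seeded stratified 5-fold cross-validation
(`cv_accuracy()`); the original validation protocol is likewise
unpublished.

## Hybridization

`hybridize(ckm, pm, cohort)` runs `coverage(ckm, cohort)`, groups the
uncovered records by failure node, and grafts one subtree per distinct
failure point:

* **Missing failures** (the typical case): the subtree is attached as
  the node's `na_branch`.
* **Domain-gap failures** (a present value matching no branch — only
  possible for hand-built, non-conforming trees): a new branch is added
  over each gap interval, and intervals no record fell into get a
  majority-class leaf so the node ends up fully partitioned.

The grafted subtree is *re-fit* on the uncovered sub-population rather
than copied verbatim from the PM: the records that reach a failure point
are a conditional slice of the cohort (they lack the tested attribute,
and they already satisfied every test above the failure point), and a
subtree fit on that slice over the still-usable attributes reflects the
conditional distribution there.  Labels come from the gold standard
where present, otherwise from dropping the records down the PM.  Groups
smaller than `min_samples_leaf` get a majority-class leaf instead of a
subtree (micro-grafts overfit); an entirely unlabeled group falls back
to a no-HF leaf.  Every grafted node carries provenance `grafted`.

Two properties hold by construction and are verified property-style in
the test suite over random model/cohort pairs:

* **Coverage monotonicity** — grafting only adds paths, so
  `coverage(R-CKM) ≥ coverage(CKM)`, with equality 1.0 on the
  hybridization cohort itself (grafted subtrees are total).
* **Expert precedence** — no existing node, test or leaf is modified,
  so every record the CKM decided receives the identical diagnosis from
  the R-CKM.  The PM never re-decides a covered case.

Rule extraction (`extract_rules()`) yields one conjunctive rule per
root-to-leaf path; the rule count equals the leaf count, and rules are
mutually exclusive.  Dedicated `na_branch` traversals emit an
"attribute is Missing" term; a branch that also receives *routed*
Missing values gets an `or_missing` flag on its term (a separate Missing
rule would duplicate the shared subtree's leaves and break the
leaf-count identity).  The exported JSON rule base keeps the
logic/condition/action intent of Medical Logic Module-style knowledge
exchange; formal Arden-syntax slot grammar and terminology-standard
bindings are out of scope, save for an optional attribute → code map
carried through to the export.

## The synthetic cohort generator

The clinical data behind the method are not public, so
`table1_default_spec()` defines a seeded generative stand-in
parameterized from the published per-phenotype summary table of the
598-patient test cohort: class priors 199/63/228/108
(HFrEF/HFmrEF/HFpEF/no-HF), per-class means and SDs for nine continuous
attributes, per-class prevalences for five binary ones.  Modeling
choices:

* Continuous attributes are truncated normals (truncated to the
  attribute's valid range), sampled by inverse-CDF, so sample moments
  converge to the analytic truncated-family expectations the tests
  check.
* NT-proBNP is heavily right-skewed physiologically, so it uses a
  lognormal matched to the printed arithmetic mean and SD.
* LVEF is truncated per class to [5, 40), [40, 50) and [50, 85], making
  the generative labels consistent with the phenotype definitions.
  No-HF is truncated to [50, 85] as well — a modeling choice (the
  controls are taken to have preserved systolic function), configurable
  and not a claim about the source cohort.
* Attributes are sampled independently within class: the summary table
  publishes only marginals, so no correlation structure is asserted.
* GLS is generated for every record; the source cohort measured it in a
  subset only, which a per-attribute missingness rate reproduces when
  wanted.
* Missingness is 0 by default and injected MCAR per attribute
  (`inject_missingness()`), since exercising Not-Available paths is a
  study condition, not a property of the summary table.

What passing tests on this generator do **not** show: robustness to
correlated attributes, informative (non-MCAR) missingness, label noise
in the gold standard, or distribution shift — real-cohort phenomena the
generator deliberately does not model.

## Evaluation conventions

`evaluate()` builds the 4×4 confusion matrix in the fixed label order,
overall and per-gold-class concordance (percent agreement), sensitivity
and specificity of the binary HF-vs-no-HF collapse, and the φ
(product-moment on 0/1 codes) association.  Uncovered predictions are
excluded from the metrics by default and reported separately; for
`compare_engines()` the default flips to scoring them as discordant,
because engines of different coverage must be compared on the same
denominator.  `summarize_cohort()` reproduces the classical
two-group table: pooled-variance t-tests for continuous attributes and
the uncorrected χ² test with Fisher's exact fallback exactly when an
expected cell count is below 5.

## The standard experiment, and a known limitation

The package's reference experiment (also what `scripts/acceptance.R`
reruns) generates 600 training and 598 test records from the default
spec with 10% MCAR missingness, induces the PM on the training set,
hybridizes, and compares expert, ML and hybrid engines on the test set.
Problem sizes throughout the test suite (600-record inductions, 100
random hybridization triples, 2000-record moment checks) were chosen so
the whole suite runs in about a minute while keeping the statistical
checks well-powered.

The hybrid engine dominates the expert engine by construction.  It does
**not** dominate the standalone learner on this synthetic world, and the
reason is instructive: the generator gives the no-HF class the published
marginals — 81.5% of controls symptomatic, 46% with abnormal ECG, LAVI
31.2 ± 8.5 (so roughly a third ≥ 34) — which makes the guideline
evidence criteria fire for most controls, capping the expert model's
specificity near 0.2 against *generative* gold labels; meanwhile the
learner exploits the enormous NT-proBNP separation between no-HF
(82 ± 68 pg/L) and HFpEF (5595 ± 9306 pg/L) almost perfectly.  Because
the hybrid grants the expert precedence on covered records, it inherits
that specificity ceiling.  In the original clinical setting the gold
standard *was* the specialists whose reasoning the expert model encodes,
which is why the hybrid led there.  The package reports what its own
computations produce; the comparative ordering between hybrid and ML is
a property of the gold-standard choice, not of the grafting algorithm.

## Numerical and degenerate-input choices

* Split-decrease comparisons use a 1e-12 tolerance; equal-decrease ties
  are resolved by schema order then threshold, so induction is fully
  deterministic (no RNG).
* All randomness (generation, missingness, CV folds) is scoped with
  `withr::with_seed`, so nothing perturbs or depends on the caller's RNG
  state, and a spec (including its seed) reproduces its cohort
  byte-for-byte through CSV.
* Coverage of an empty cohort is 1 by convention (vacuous truth).
* `rank_algorithms()` with a degenerate (zero-range) criterion
  normalizes accuracy to 1 and the two counts to 0, so a lone candidate
  scores exactly the sum of the weights.
* Single-class training data yield a single majority leaf and all-zero
  feature importances.
* Knowledge-model JSON is written with 17 significant digits so
  thresholds survive the round-trip exactly.

## Known limitations

* The schema fixes the 14 attributes; the original system's full
  attribute list beyond the published summary-table rows is not
  reproduced, and extending the schema is a code change, not
  configuration.
* Grafting fills Missing paths and domain gaps; it never revises expert
  decisions, so systematic expert errors are inherited by design.
* The MLM-style export is a JSON analogue, not a standards-conformant
  artifact.
* Published headline accuracies from the original clinical cohorts are
  not reproducible here: that data is private, and the synthetic
  stand-in matches marginal summaries only.
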