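---
title: "Computable phenotyping from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computable phenotyping from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotext)
```

## The problem

Many clinical study cohorts cannot be defined from structured EHR data
alone: symptoms, imaging findings, and negated statements ("denies pelvic
pain") live in free-text notes. A computable phenotype over notes is a
classification problem — given a patient's notes, assign a class such as
case/noncase or symptomatic/asymptomatic. phenotext implements a deliberately
transparent pipeline for this problem: the features are regular expressions a
clinical expert writes and can read, and the aggregation from text to a
patient-level vector is a fixed, auditable rule.

## The model

**Features.** A feature is a named regular expression with a per-feature case
sensitivity flag. The engine uses the Perl-compatible dialect (PCRE), which
covers the idiom clinical feature authors actually write: explicit case
alternation (`(D|d)iabetes`), bounded gaps (`(denies|no).{0,35}pelvic pain`),
character classes, optional groups, and long co-occurrence windows (up to
hundreds of characters). Feature order is significant: it fixes the
coordinate order of every vector downstream. Every pattern is compiled when
the feature set is constructed, and a pattern that does not compile is an
error carrying the compiler's diagnostic — expressions transcribed from print
are a known source of corrupted patterns, and silently accepting one would
quietly zero out a coordinate.

**Aggregation.** For each sentence of each note, the engine counts the
non-overlapping matches of each feature (left-to-right scan; after a match
the scan resumes at the match end). Counts are summed over a note's sentences
to give the note vector, and a patient's vector is the arithmetic mean of
their note vectors. The mean is order-invariant and invariant to duplicating
every note; each coordinate lies within the range of that patient's per-note
counts. Notes with empty text contribute zero vectors and still count in the
denominator — an empty note is a real observation of absence. The patient
vector is the unit of classification.

**Sentence segmentation.** The counting unit is the sentence, so segmentation
is part of the model. The rule is deterministic and dependency-free: hard
newlines always end a sentence; within a line, a run of `.?!` followed by
whitespace ends a sentence unless the token it terminates is on a published
abbreviation list (`Dr.`, `pt.`, `vs.`, `e.g.`, ... — see
`clinical_abbreviations`). Text with no sentence punctuation is a single
sentence, which keeps long-range window patterns usable on unpunctuated note
sections (problem lists, imaging report fragments). Because matching happens
after segmentation, no pattern can match across a sentence boundary; the gap
quantifier in a window pattern therefore bounds *within-sentence* distance.

**Classifiers.** Four standard families consume the patient vectors through
one contract (fit on labeled vectors; emit per-class probabilities summing
to one):

| algorithm | backing implementation | scores | defaults |
|---|---|---|---|
| `linear_svm` | e1071 (libsvm) | Platt-type logistic fit on the training margin | `cost = 1`, features standardized with training-data center/scale |
| `gaussian_nb` | e1071 | class-conditional Gaussian densities | per-class sd floored at `1e-6` |
| `decision_tree` | rpart (CART) | leaf class frequencies | `minsplit = 5`, `cp = 0.01` |
| `random_forest` | randomForest | mean of per-tree votes | `ntree = 100`, `nodesize = 1` |

Raw mean counts are used unscaled except for the SVM, whose margin-based
objective is scale-sensitive; its standardization is fitted on training data
only, so no test information leaks. The Gaussian-NB standard-deviation floor
exists because all-zero count columns are routine in this domain (a feature
that never fires on one class) and a zero variance makes the density
degenerate. If *every* feature is constant across the training set there is
no signal at all; the random-forest backend's split search cannot terminate
on such input, so the fit degenerates explicitly to the training class prior
(the only defensible model in that situation). Multi-class problems are
supported natively by all four families; nothing assumes a binary phenotype.

**Predictions and confidence.** The predicted label is the argmax of the
class scores and the confidence is that score; exact ties resolve to the
class earliest in the model's sorted `class_names` — a documented, boringly
deterministic rule. Confidence supports selective classification:
`confidence_filter()` accepts predictions at or above a cutoff and routes the
rest to manual review, and `confidence_curve()` tabulates the accepted-volume
versus accepted-accuracy trade-off at every observed confidence value.

## Evaluation

**Cross-validation** partitions patients (never notes) into k-fold,
stratified k-fold, or leave-one-out folds, trains on each complement and
predicts the held-out fold, so each patient is scored by a model that never
saw it. Stratified 10-fold with a random forest is the default setting, the
usual choice for imbalanced phenotype corpora.

**Blinded held-out evaluation** seals the test labels into a vault object:
predictions can be made on the blinded set, but any metric computation
before an explicit `unblind()` is an error, and unblinding is idempotent and
logged. This makes the blinding discipline mechanical instead of procedural.

**Metrics.** From the confusion matrix (rows = truth, columns = prediction)
the report derives accuracy and per-class one-vs-rest sensitivity,
specificity, PPV, NPV, and F1. A zero-denominator ratio (NPV when nothing is
predicted negative, say) is reported as `NA`, never 0 — an undefined rate is
not a zero rate. AUROC is computed from midranks, which is exactly all-pairs
concordance with ties counted half; for more than two classes it is
one-vs-rest macro-averaged, a documented generalization rather than a claim
about any particular study design. Out-of-fold accuracy (training
iterations) and held-out accuracy (after unblinding) are labeled distinctly
in reports. Accuracy is overall fraction correct.

## The synthetic-data generator

Real gold-standard corpora are institution-bound, so the generator produces
corpora with the statistical structure the classifier consumes: classes that
differ in per-sentence phrase-emission probabilities, multi-note patients,
neutral filler, near-miss decoys, and negated surface forms. Three design
choices keep tests honest:

* every phrase bank is verified at build time — positive phrases must match
  their feature, decoys must match *nothing*, filler must be neutral — so
  fixtures can never silently decouple from the regex dialect;
* at most one phrase is planted per sentence (emission probabilities are
  mutually exclusive per sentence and must sum to ≤ 1 per class), so the
  planted per-note counts are exact ground truth, verified end-to-end
  against the engine;
* negated surface forms ("denies pelvic pain", "no pelvic pain today") are
  drawn per class: the negation benchmark gives both classes the same
  emission rate and makes only the surface form differ, which is precisely
  the situation where a keyword-only feature set must fail and a
  negation-aware one succeed.

The bundled benchmark suite fixes the study conditions: a balanced separable
design (2 × 25 patients, emission 0.3 vs 0.01, 3–5 notes of 4–8 sentences —
short-note extracts typical of a phenotyping pull), an imbalanced ≈1:10
design (20 vs 200 patients, emission 0.08 vs 0.01, 2–4 notes of 3–6
sentences) whose weak signal produces the characteristic near-1 specificity
with degraded sensitivity, and the negation design (2 × 25, emission 0.3 in
both classes, negation rate 1 for the asymptomatic class). These sizes are
the problem sizes the test suite and the acceptance script run at.

What the generator does **not** emulate: narrative coherence, vocabulary
drift across note types, misspellings, copy-forward duplication, template
boilerplate, or section structure. Passing tests therefore demonstrate that
the pipeline is correct and that the classifiers recover planted signal
under the stated statistical conditions — not that any particular feature
set will perform comparably on real notes, where feature authorship and
iteration against misclassified patients carry most of the difficulty.

## Numerical and design choices

* **Counting rule**: non-overlapping leftmost matches. Overlapping counting
  is defensible but less reproducible across engines; the choice is
  documented so counts are exactly specifiable. Note that greedy gap
  quantifiers mean one match can swallow a later phrase occurrence within
  the same sentence — a property of the dialect, surfaced in the tests.
* **Case sensitivity** defaults to sensitive because feature authors encode
  case deliberately; a per-feature flag overrides.
* **Label conflicts** within a patient are hard errors, not majority votes:
  silent voting would corrupt the gold standard at its most trusted point.
* **Split and fold assignment** are seeded and patient-level; stratified
  splitting uses the closed-form per-class allocation (rounded, clamped so
  both sides are nonempty).
* **Determinism**: every stochastic step (splits, folds, per-fold model
  fits, generation) takes an explicit seed; pipeline commands write
  timestamp-free manifests so identical configurations reproduce reports
  byte for byte.
* **Degenerate inputs**: empty notes vectorize to zero; an empty corpus, a
  single-class training set, an unlabeled patient in a split, and a
  feature/model mismatch at prediction are all explicit errors.

## Limitations

The package deliberately excludes linguistic negation detection, stemming,
and ontology mapping — negation is handled entirely by user-authored
patterns, which is transparent but puts the burden of coverage on the
feature author. Sentence segmentation is rule-based; pathological punctuation
can over- or under-segment, which shifts window-pattern semantics. The SVM's
probability calibration is fitted on small training folds and can be
unstable for very small classes. AUROC beyond two classes is a macro
average, which weights rare classes equally with common ones.
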