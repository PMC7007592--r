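# phenotext

Computable phenotyping from free-text clinical notes with
regular-expression features and standard machine-learning classifiers.

## The problem

Cohort identification often hinges on information that never reaches
structured EHR fields: symptoms, imaging findings, and negated statements
("denies pelvic pain") live in the notes. phenotext treats phenotyping as a
patient-level classification problem with deliberately transparent inputs:
the features are named regular expressions a clinical expert writes, and the
text-to-vector transformation is one fixed, auditable rule.

For each sentence *s* of each note *d* of patient *p*, and each feature *j*
with pattern *r<sub>j</sub>*, the engine counts non-overlapping matches
*c<sub>j</sub>(s)*. Aggregation is

> note vector: x<sub>j</sub>(d) = Σ<sub>s∈d</sub> c<sub>j</sub>(s)  
> patient vector: x<sub>j</sub>(p) = (1/|D<sub>p</sub>|) Σ<sub>d∈D<sub>p</sub></sub> x<sub>j</sub>(d)

The patient vectors feed any of four classifier families — linear SVM,
Gaussian naive Bayes, decision tree, random forest — behind one contract:
per-class probability scores summing to one, with the prediction's
confidence equal to the top score. Evaluation covers patient-level
cross-validation (k-fold, stratified, leave-one-out), blinded held-out sets
whose labels are sealed until an explicit, logged `unblind()`, diagnostic
metrics (sensitivity, specificity, PPV, NPV, F1, rank-statistic AUROC), and
confidence-cutoff abstention analysis for routing low-confidence patients to
manual review. A synthetic corpus generator with verified planted phrases
makes the entire pipeline testable without access to clinical data.

## Worked example

```r
library(phenotext)

# a bundled benchmark: 25 cases vs 25 noncases, two regex features,
# class-dependent planted phrases in neutral filler text
bench <- make_benchmark_suite(seed = 42)$balanced
pv <- vectorize_patients(bench$corpus, bench$features)
head(pv, 4)
#> # A tibble: 4 × 5
#>   patient_id label n_notes `pelvic pain` `ear tubes`
#>   <chr>      <chr>   <int>         <dbl>       <dbl>
#> 1 p0001      case        3         1.33         1.67
#> 2 p0002      case        3         0.667        2.33
#> 3 p0003      case        3         2            3
#> 4 p0004      case        3         0.333        2.67

cv <- crossval(pv, algorithm = "random_forest",
               cv_method = "stratified_kfold", n_folds = 10, seed = 42)
glance(cv)
#> # A tibble: 1 × 7
#>   algorithm     cv_method         n_folds n_patients accuracy mean_confidence  seed
#>   <chr>         <chr>               <int>      <int>    <dbl>           <dbl> <int>
#> 1 random_forest stratified_kfold       10         50        1           0.955    42

compute_metrics(confusion_matrix(cv$predictions), scores = cv$predictions)
#> <metrics_report> accuracy 1.000 on 50 patients (0 abstained), AUROC 1.000
#> # A tibble: 2 × 7
#>   class   n_true sensitivity specificity   ppv   npv    f1
#>   <chr>    <int>       <dbl>       <dbl> <dbl> <dbl> <dbl>
#> 1 case        25           1           1     1     1     1
#> 2 noncase     25           1           1     1     1     1
```

Each row of `pv` is one patient: `pelvic pain = 1.33` means that patient's
notes average 1.33 matches of that feature per note. `accuracy` in
`glance(cv)` is out-of-fold: every patient was predicted by a model trained
without them. The metrics report gives per-class one-vs-rest diagnostics;
`confidence_filter(cv$predictions, 0.55)` would split these predictions into
those confident enough to accept and those to review manually (here all 50
clear the cutoff).

Real corpora enter through `read_corpus()` (a JSON array of note records
with the gold label in a designated metadata field) and `read_features()`
(JSON or two-column CSV of named patterns); `split_corpus()`,
`blind_labels()`, `evaluate_blinded()`, `unblind()`, and `score_blinded()`
implement the blinded held-out workflow. The same pipeline is scriptable via
the installed command-line tool (`inst/cli/phenotext`) with subcommands
`generate`, `vectorize`, `train-cv`, `evaluate`, and `unblind`, each writing
a manifest that reproduces its outputs byte for byte.

## Documentation

The methods vignette (`vignettes/phenotyping-from-notes.Rmd`) describes the
aggregation model and its assumptions, sentence segmentation, classifier
defaults, the confidence/abstention machinery, what the synthetic generator
does and does not emulate, and the package's numerical design choices.
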