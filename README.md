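# notephen

Rule-based phenotyping from free-text clinical notes.

Most of what an electronic medical record knows about a patient sits in
unstructured text — history & physical examinations, daily progress
notes, discharge summaries. Researchers who need a per-patient binary
flag ("did this patient have endocarditis during the index admission?")
usually fall back on billing codes, which are designed for
reimbursement, not science: their sensitivity for research definitions
is poor, especially for chronic conditions that coders omit at the index
admission. `notephen` is for investigators who want to build those flags
directly from the notes, with every intermediate step inspectable,
auditable, and replayable — a deliberately transparent alternative to
black-box language models.

## The pipeline

1. **Search** (`find_instances`). A condition is described as a search
   pattern: explicit roots with prefix semantics (`delir*` matches
   *delirium* and *delirious*), exact synonyms and abbreviations
   (`pneumonia`, `pna`), and multiword phrases (`central cord
   syndrome`). Every non-overlapping mention in the corpus is stored
   with its surrounding tokens in a plain-text, fully searchable
   intermediate database; the subset of relevant notes is cached so
   re-searches are fast and provably equivalent.
2. **Categorize** (`categorize_corpus`). Each mention's meaning in
   context is resolved by querying a cue-phrase library mapping word
   groups to five categories: acutely present ("admitted with"),
   historical/chronic ("history of"), negated ("no evidence of"), under
   evaluation ("suspected"), or a different sense of the term entirely
   (*decubitus xray* vs *decubitus ulcer*). Mentions the library cannot
   classify are reviewed keyword-in-context at expanding window widths
   (`review_session`); every decision labels all identical windows at
   once and becomes a new library rule, so the library grows with each
   project.
3. **Audit** (`audit_report`). Full or seeded-sample reports of every
   classification, for balancing precision against effort.
4. **Export** (`aggregate_patients`, `write_dataset`). A CSV of patient
   key plus one binary variable per condition. Negated,
   different-meaning, and ambiguous mentions count as absent; the
   acute-only or "ever" (acute + historical) mapping is configurable.

An **evaluation** module computes sensitivity and specificity against a
gold standard with Wilson score (default), t-quantile, or exact
intervals, compares labeling sources by pooled t-test, and tallies
comparator false negatives caused by chronic-condition omission. A
**synthetic corpus generator** (`simulate_corpus`) emulates multi-note
patients, abbreviations, note bloat, and ICD-style comparator errors
with known ground truth, so the entire pipeline is testable end to end
with no access-restricted data.

## Worked example

Simulate a 200-patient cohort, run the pipeline for pneumonia, and
check it against the generator's gold labels:

```r
library(notephen)

sim    <- simulate_corpus(sim_config(n_patients = 200, seed = 7))
corpus <- as_note_corpus(sim$notes)

pat <- compile_pattern("pneumonia", c("pneumonia", "pna"))
db  <- find_instances(corpus, pat)
db
#> <intermediate db> condition: pneumonia | instances: 122 | relevant notes: 82

res <- categorize_corpus(db, default_rule_library())
table(res$db$instances$category)
#>      ACUTE_PRESENT  DIFFERENT_MEANING HISTORICAL_CHRONIC            NEGATED
#>                 27                 10                 17                 55
#>   UNDER_EVALUATION
#>                 13

ph <- aggregate_patients(res$db, export_config(ever_present = TRUE),
                         unique(corpus$patient_id))
cm <- confusion(ph$flags, sim$gold[, c("patient_id", "pneumonia")])
sens_spec(cm)
#>   metric      point ci_low ci_high level method     k     m
#> 1 sensitivity     1  0.839       1  0.95 wilson    20    20
#> 2 specificity     1  0.979       1  0.95 wilson   180   180
```

All 122 mentions are classified by the starter library (55 of them
negations — most pneumonia mentions in real notes are "no evidence
of"-style), and the exported flags reproduce the simulated truth
exactly: 20/20 true positives, 180/180 true negatives.

The package also ships a published per-condition benchmark comparing
ICD-9 codes and note extraction against a chart-review gold standard
for eleven ICU conditions:

```r
bench <- validation_benchmark()
round(mean_accuracy(bench$icd_sensitivity)$mean, 2)   # 0.65
round(mean_accuracy(bench$note_sensitivity)$mean, 2)  # 0.98
compare_means(bench$icd_sensitivity, bench$note_sensitivity)$p
#> 0.0003926545
```

Note extraction is dramatically more sensitive than billing codes at
equal specificity — codes miss real (especially chronic) conditions far
more often than notes do.

## Vignette

`vignettes/notephen-methods.Rmd` documents the method in full: the
five-category model and its assumptions, the cue-matching precedence
order, preprocessing and tokenization rules, review-workflow mechanics,
interval and test choices, what the synthetic generator does and does
not emulate, and known limitations.
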