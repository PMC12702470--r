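---
title: "Rule-based note phenotyping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based note phenotyping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notephen)
```

## The problem and the model

`notephen` converts free-text clinical notes into per-patient binary
condition flags. The underlying model is deliberately simple and fully
inspectable: a condition mention's meaning is assumed to be determined
by *cue phrases* in a small token window around it. Five meanings are
distinguished — acutely present, historical/chronic, negated, under
evaluation, and "different sense of the term" — plus an explicit
`UNCATEGORIZED` state for mentions no rule covers. A patient's flag is
then a pure function of the categories of their mentions: present iff
at least one mention carries a category in the configured "present"
set.

The assumptions this model makes about clinical text:

* **Locality.** The words that fix a mention's meaning sit within a few
  tokens of it. Sentence boundaries are *not* parsed (normalized note
  text often lacks reliable punctuation); the `max_gap` parameter is
  the sole scope limiter. A cue more than `max_gap` tokens away never
  fires.
* **Redundancy.** Electronic notes are long and repetitive ("note
  bloat"): a clinically real condition is mentioned in several notes
  with affirming context, so a single affirmed mention is sufficient
  evidence. This is also why recall against research definitions can
  exceed that of billing codes, which depend on a coder deciding a
  condition is billable for the index admission.
* **A closed meaning vocabulary.** The five categories cover
  retrospective chart-review designs. Mentions outside the library stay
  visibly `UNCATEGORIZED` and block export by default; silence is never
  interpreted.

## Text preprocessing

Notes are normalized once at corpus load: non-ASCII punctuation is
mapped to ASCII (length-preserving, so character offsets stay valid),
text is lower-cased, tokens are split on whitespace with
leading/trailing punctuation stripped, and internal hyphens/periods are
kept so shorthand like `x-ray` and `1.5` survives. Slashes separate
words (`and/or`) unless both neighbors are alphanumeric runs of at most
two characters (`s/p`, `w/o`), in which case the token is kept and the
slash standardized to `-`. Every token records a 0-based half-open
character span into the raw text, and normalizing a span's raw text
reproduces its token — the property the test suite enforces.

Stop-word removal uses a small fixed list of ~25 function words, with a
**protected set that always wins**: the negation/uncertainty markers
(`no`, `not`, `without`, `denies`, `negative`, `doubt`) and every word
occurring in the starter cue library (hence `of`, `for`, `with`, `as`,
`a`). Two parallel streams are kept per note: the filtered stream is
what search patterns match against, while contexts and cue matching use
the full normalized stream — cue phrases like "no evidence of" contain
stop words and must remain matchable. This dual-stream design is why
stop-word removal can never destroy a cue.

The stemmer is a one-pass, longest-suffix-first stripper over a fixed
ordered list that includes Latinate clinical suffixes (`-itis`,
`-itus`, `-ium`, `-ious`, `-ia`, ...), with a minimum remaining stem of
four characters. It maps inflection families like
*delirium*/*delirious* to `delir` and *decubitus* to `decub`, and
leaves short abbreviations (`pna`) untouched. It is intentionally not a
full Porter stemmer: search patterns use *explicit* prefix semantics
(`delir*`), so the stemmer only needs to be deterministic and
prefix-preserving, which the suite asserts on random token samples.

## Search

`find_instances` scans the filtered stream left to right with greedy
non-overlapping matching: at each position the longest match wins
(multiword phrase ≥ literal/stem), and scanning resumes after it, so a
multiword match can never be double-counted through its own interior.
Matches at a note boundary simply truncate their context. Each mention
is stored with up to `window` tokens of full-stream context per side
(default 12, enough to contain every starter cue with margin), in a
plain-text intermediate database keyed by a content fingerprint of the
corpus; loading a database against a modified corpus warns about
staleness. Re-searching only the cached relevant-note subset is
guaranteed (and tested) to reproduce the full-corpus result.

## Cue matching and precedence

A rule is a normalized cue phrase, a side (`before`/`after`/`either`),
a `max_gap` (default 5 tokens — starter cues are adjacent phrases; 5
tolerates bloat insertions), and a category. Cues may contain one
`<term>` placeholder, turning them into collocation rules anchored on
the match itself (`<term> xray`, `joint <term>`, with a tighter default
gap of 2 because collocations are adjacency phenomena).

When several rules fire on one mention, the winner is chosen by a fixed
precedence, in order: (1) different-meaning placeholder rules win
outright — they redefine the entity, so no amount of surrounding
affirmation matters; (2) smallest token distance between cue and match;
(3) longest cue; (4) the conservative category order different-meaning
> negated > under-evaluation > historical > acute, which biases ties
toward "absent" and hence against false positives; (5) smallest
rule id. The order is deterministic and auditable, and the suite checks
it against an exhaustive (rule, position) enumeration oracle on
randomized contexts.

## The review workflow

Mentions the library cannot classify are grouped by identical
keyword-in-context windows at half-width *k* and presented largest
group first; one decision labels every member and is distilled into a
new rule. The default width schedule is 3, 5, 8, 12 (capped by the
stored window): short windows first maximize collapsing, wider windows
disambiguate the remainder. The learned rule uses the shortest token
run adjacent to the term that occurs in no other open group's window
(preferring the before side), with `max_gap = k`; if no shorter cue is
unique, the full window becomes a placeholder collocation rule.
After each width pass the remainder is re-categorized with the grown
library, so the uncategorized count is non-increasing by construction.
Decision sources are plain functions, and a recorded transcript
replayed against the same inputs reproduces every output artifact
byte for byte — interactive review and scripted tests share one code
path.

## Export and evaluation

The default present-set is `{ACUTE_PRESENT}` (acute phenotypes);
`ever_present = TRUE` adds `HISTORICAL_CHRONIC` for "ever had it"
phenotypes. Negated, different-meaning, and under-evaluation mentions
map to absent, as do uncategorized mentions *only* when explicitly
requested — the default is to refuse export until review is finished.
Every screened patient appears in the dataset (patients without
mentions get 0), because specificity needs true negatives.

Sensitivity and specificity use the Wilson score interval by default:
accurate phenotyping lives at proportions near 1, exactly where the
normal/t approximation misbehaves (its upper bound caps at the point
estimate when $\hat p = 1$). The t-quantile interval
($\hat p \pm t_{1-\alpha/2,\,m-1}\sqrt{\hat p(1-\hat p)/m}$, clipped to
[0, 1]) and the exact Clopper–Pearson interval are selectable for
compatibility with reports that used them. Coverage of the Wilson
interval is verified by simulation at 2,000 replications of 100
Bernoulli trials at p ∈ {0.5, 0.9, 0.98}; 100 trials per replication is
the scale at which the interval's nominal 95% behavior holds across all
three operating points (at substantially smaller samples the exact
binomial coverage of *any* 95% proportion interval oscillates below
93% near p = 0.98).

Labeling sources are compared per condition with equal weight: the mean
of per-condition point estimates with its SEM, and a pooled-variance
two-sided t-test (Welch's form selectable). Comparator false negatives
for patients with chronic-history status are tagged `chronic_omission`
and tallied per condition — the characteristic failure of billing codes
for chronic disease.

The package ships a published eleven-condition ICD-vs-note benchmark
(`validation_benchmark()`, with `chronic_omission_benchmark()` for the
chronic-omission tallies) whose column means and t-tests the acceptance
script recomputes through these functions.

## The synthetic generator

`simulate_corpus` emulates the statistical structure the pipeline is
meant to survive, not clinical language itself. Per patient: one
history & physical, one to five progress notes, one discharge summary
(single-admission patients only — acute/chronic distinctions blur
across closely spaced admissions). Gold condition status is Bernoulli
with configurable prevalence (default 0.10, a typical screened-cohort
rate); positive patients get a guaranteed anchor mention whose category
is historical with probability `chronic_fraction` (default 0.5) and
acute otherwise, plus Poisson extras drawn from a five-category mix;
negative patients get only negated / under-evaluation /
different-meaning distractors at a Poisson rate (default 0.3). Mentions
use the starter cue inventory verbatim with the cue adjacent to the
term; surface forms are drawn from the condition's term list, so
abbreviations (`pna`) are exercised. Sentences are padded with a filler
vocabulary disjoint from all cue words and condition terms, and
sentences carry at least three padding tokens on each side, so
cross-sentence cue leakage is impossible at the default gaps — which is
what makes exact label recovery a meaningful test rather than an
accident. Note bloat duplicates whole sentences (truth is logged after
duplication, so bloat never changes gold labels, only mention counts).

The comparator labeling flips gold positives to 0 with probability
`fn_rate` (+ `chronic_fn_boost` when chronic) and gold negatives to 1
with probability `fp_rate` — defaults 0.25/0.05/0.15, chosen so the
expected comparator sensitivity, $1 - (0.25 + 0.5 \times 0.15) =
0.675$, sits in the range the benchmark table reports for ICD coding.
The degradation experiment in the acceptance script runs this model at
2,000 patients with prevalence 0.5 — an enriched validation-cohort
design that puts ~1,000 patients on each side of the gold split, so the
observed sensitivity estimates the flip-model expectation with a
standard error of ~0.015.

What the generator does **not** emulate: real clinical syntax, spelling
errors and OCR noise, cue phrases outside the starter inventory,
cross-sentence discourse (e.g. "ruled out" appearing a paragraph
later), multi-admission temporality, and inter-annotator disagreement
in the gold standard. Passing the recovery tests therefore demonstrates
that the machinery is correct — search finds what is there,
categorization applies the library faithfully, export maps categories
as configured — not that the starter library is sufficient for any
real corpus. On real notes the uncategorized remainder and the review
workflow carry the accuracy burden.

## Numerical and degenerate-input conventions

* Character offsets are 0-based half-open; token indices 0-based.
* Empty note text is legal and yields zero tokens, not an error.
* A metric with a zero denominator (no gold positives/negatives) is an
  explicit error naming the metric, never `NaN`.
* Instances are sorted by (patient, note, position); datasets by
  patient key with condition columns lexicographic; identical inputs
  produce byte-identical artifacts everywhere (all file writers use
  fixed `\n` line endings).
* Audit sampling is uniform without replacement under an isolated seed
  (`withr::with_seed`), so it never perturbs the caller's RNG state.
* Report display rounds to 2 decimals, round-half-even; stored values
  are never rounded.

## Problem sizes

The test suite exercises the full pipeline at 20–150 simulated
patients per property, end-to-end recovery at 500 patients × 2
conditions, the comparator-degradation experiment at 2,000 patients,
and interval coverage at 2,000 × 3 replications; the acceptance script
uses the same sizes. These are the scales at which the stochastic
checks have comfortable analytic margins (binomial envelopes of ±2–3
standard errors) while a full run of suite plus script stays in the
tens of seconds on one core.

## Known limitations

* Cue scope is a token window, not a parse: a negation can
  theoretically bind across what a human reads as a sentence boundary
  if it falls within `max_gap`. The conservative precedence order and
  the small default gaps limit, but cannot eliminate, this.
* The starter library is a seed, not a solution; project libraries
  grown through review are where real-world accuracy comes from.
* No concept normalization (UMLS/SNOMED): a condition is whatever its
  term list matches.
* The evaluation module treats the gold standard as error-free; it
  estimates operating characteristics, not agreement models.
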