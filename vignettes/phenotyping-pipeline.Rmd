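---
title: "Phenotyping ICU respiratory-support therapies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping ICU respiratory-support therapies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resppheno)
```

## The phenotyping model

An ICU encounter is classified by which respiratory-support therapies it
received and in what order: invasive mechanical ventilation (IMV),
noninvasive positive pressure ventilation (NIPPV), high-flow nasal
insufflation (HFNI), one of four two-therapy sequences, or none. The unit of
analysis is the *first* ICU encounter of each adult patient; later
encounters and under-18s are excluded before anything else happens.

Evidence comes from nine relational source tables whose rows carry an
encounter id, an integer offset in minutes from ICU admission (negative
offsets are legal — pre-admission orders exist — and are ordered like any
other), and free-text descriptive columns. Each row is normalised into a
*constructed concept*, `"Source = <table>; Concept = <fields>"`, with the
table's descriptive columns joined by `": "` in a fixed order. Concept
identity is exact, case-sensitive string equality. We deliberately do no
lowercasing, whitespace collapsing (beyond trailing line breaks, and
flattening multi-line note text onto one line) or vocabulary mapping: the
premise of the pipeline is that raw EHR strings go straight to the
classifier, and any normalisation would silently merge concepts that a
reviewer — human or model — might judge differently.

### Therapy criteria and the interval rule

Within one encounter, with records restricted to the selected concepts:

* **IMV received**: at least two records whose concept indicates IMV *and*
  at least one record whose concept is an intubation-related medication
  (induction agents, neuromuscular blockers, continuous sedatives). The
  medication co-requirement applies to IMV only; two charting mentions of a
  tube without any supporting pharmacology are treated as noise.
* **Noninvasive support received**: at least two records whose concepts
  indicate NIPPV or HFNI, pooled. The episode counts as HFNI when at least
  one of those records is an HFNI concept, as NIPPV otherwise.
* **Interval rule**: if an IMV episode exists, noninvasive records with
  offsets in the closed interval from the first to the last IMV record are
  removed (they are usually weaning trials during ventilation) and the
  noninvasive criteria are reassessed on what remains.

Episode bounds are the min/max offsets of the supporting therapy records;
classification then reads start order: no episode is "None", one episode is
"`<therapy>` Only", a noninvasive episode starting before IMV is
"NIPPV/HFNI Failure", and IMV starting first is "IMV to NIPPV/HFNI".

Two readings of the published criteria deserve a note. First, the NIPPV and
HFNI criteria are, taken literally, mutually unsatisfiable (NIPPV demands
*no* HFNI records while HFNI demands the NIPPV criterion *plus* an HFNI
record). We adopt the only consistent reading: one pooled noninvasive
episode of ≥ 2 records, labeled HFNI exactly when an HFNI concept is
present. Second, "between IMV records" is read as the overall IMV span, not
gaps between consecutive IMV records; the overall span is the weaker
assumption and is idempotent under re-application.

### Degenerate inputs

Anything the eight classes cannot express is a typed
`resppheno_unclassifiable` error rather than an arbitrary choice: two
episodes starting at the same offset (the data give no order), duplicate or
more than two episodes. Silent tie-breaking here would corrupt ground truth
downstream. Similarly, a duplicated (patient, admission-order) pair is an
ambiguity error in the first-encounter filter, and unparseable ages exclude
the encounter with a warning; the de-identification sentinel `">89"` parses
as 90 and is always an adult.

## Model-backed stages

*Concept selection* classifies each distinct concept twice — a
respiratory-therapy prompt and a medication prompt, because separating the
two tasks works better than one combined question — and ORs the two parsed
YES/NO answers. *Description phenotyping* renders each encounter's selected
concepts as a rank-numbered list (`"#: {concept}"`, ranked by first
occurrence, first-occurrence ties broken lexicographically so shuffled
input cannot change the text), deduplicates identical texts across
encounters, classifies each unique text once, and maps labels back. The
description deliberately contains only ranks and concept text — no offsets,
no identifiers — so timing is generalised to order and identical courses
share one classification.

Prompts are chain-of-thought: a definitions preamble with a `{payload}`
slot, ordered intermediate questions, and a final question whose answer is
parsed. Prompt wording is configuration, not code: templates ship as
editable YAML and the parser keys off each template's own answer marker,
taking the *last* vocabulary token after the marker's last occurrence
(reasoning text often mentions both tokens before committing). A response
with no marker or no token is the value `"UNPARSEABLE"`, not an exception;
concept tasks treat it as NO by default, the phenotyping stage keeps it
visible for audit (policy-configurable in both cases).

Backends are exchangeable behind one contract (raw text, parsed decision,
latency in seconds). The live backend speaks the Ollama HTTP API with
greedy decoding defaults (temperature 0.0, top-p 0.99) and an on-disk cache
keyed by (model tag, prompt hash), so interrupted or repeated runs make
zero new calls. The oracle backend answers concept tasks by lexicon
membership and the phenotype task by re-running the rule engine on the
description itself, using rank as the pseudo-offset. That makes the
oracle-equivalence test a genuine cross-check rather than a tautology: the
reference algorithm sees raw records with minute offsets and record-level
counts, the oracle sees a deduplicated, rank-ordered rendering, and the two
must still agree on every encounter.

## The synthetic generator

`generate_cohort()` emulates what matters to this pipeline and nothing
more: nine tables with the right columns, concept strings drawn from a
bank of realistic charting values, planted therapy episodes with the
required record counts and orderings, Poisson-distributed distractor
records (default mean 20 per encounter — irrelevant charting dominates real
EHR data), a small rate of minors (5%) and second encounters (10%) so the
cohort filters do real work, and the `">89"` sentinel at 3%. The default
phenotype mix follows the published ARF cohort composition (82.8% None,
10.5% IMV Only, 4.3% NIPPV Only, 0.7% HFNI Only, and under 1% for each
multi-therapy sequence), so class imbalance is realistic.

Three generator guarantees keep the planted truth exact under both views of
the data: therapy records within an encounter use *distinct* concepts (so
deduplicated descriptions still meet the record-count criteria), episode
windows for sequence phenotypes are disjoint in time (so rank order
preserves offset order), and interval-rule stressor records are planted
strictly inside the IMV span. "None" encounters may carry sub-threshold
evidence — a single noninvasive record, or two IMV records with no
medication — precisely so that near-misses are tested, not avoided.

What the generator does *not* emulate: misspellings and free-text variance
within a concept, inter-hospital transfers, concept strings that are
ambiguous to a human reviewer, and realistic table-specific offset
distributions. A perfect score on synthetic data therefore validates the
pipeline's mechanics and the rule engine's logic, not language-model
accuracy on real charts; on real data the interesting quantity is exactly
how far a live backend falls short of the oracle's ceiling.

## Evaluation choices

The pipeline emits hard labels, so each one-vs-rest ROC has a single
operating point and AUROC is computed as the area of the three-point curve,
(sensitivity + specificity)/2 — balanced accuracy. This is stated as an
explicit modelling assumption: with discrete YES/NO decisions it is the
only well-defined ROC construction, and it makes the identity
AUROC = (sens + spec)/2 a structural invariant the tests assert exactly.
Classes with zero true members in an evaluated cohort are reported as NA
("not applicable"), never coerced to 0 or 1, and macro averages (unweighted
means over the single-therapy/none group and the multi-therapy group) skip
them. Latency is summarised as the arithmetic mean of per-call seconds per
prompt and pooled.

For the noise-degradation check we measure the per-prompt decision AUROC of
a backend that flips each decision with probability *p* over balanced
concepts, whose expectation is 1 − *p* (0.90 at *p* = 0.1, within three
Monte-Carlo standard errors over 10,000 concepts). The OR-combined
selection decision has a different closed form (1 − 1.5*p* + *p*², ≈ 0.86
at *p* = 0.1) because a false YES on either prompt selects the concept;
the per-prompt measurement is the one that isolates backend accuracy, and
matches how per-prompt AUROCs are reported for the live models. Noise
flips are derived from a hash of (seed, task, payload), so they are seeded
and order-independent — reordering concepts cannot change a noisy run.

## Problem sizes and defaults

Test and validation runs use cohorts of 150–500 patients (the
oracle-equivalence run uses 500, about 470 eligible encounters after the
filters), a 5,000-patient cohort for the chi-square check that empirical
phenotype frequencies match the configured mix, and 10,000 balanced
concepts for the noise experiment. These sizes put Monte-Carlo error well
below the effects being asserted while keeping any single run in seconds.
The defaults that matter scientifically — phenotype mix, distractor rate,
therapy record-count thresholds, decoding settings — are documented above
and in `generator_config()`; they were fixed from the published study
conditions before validation and are not tuned.

## Known limitations

* The eight-class scheme cannot express more than one therapy transition;
  such encounters surface as unclassifiable errors by design.
* Concept identity by exact string match means real-data deployments
  should expect many near-duplicate concepts; that is faithful to the
  source design but inflates the distinct-concept count the selection
  stage must classify.
* AUROC from hard labels compresses all trade-off information into one
  operating point; it is comparable across backends here but not to
  score-based AUROCs elsewhere.
* The live backend is exercised against its HTTP contract only; model
  quality, hosting and GPU management are out of scope.
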