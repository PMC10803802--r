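---
title: "Methods: DRG prediction from discharge summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DRG prediction from discharge summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgkit)
```

## The problem

Every U.S. hospital stay billed under the inpatient prospective payment
system receives exactly one Medicare Severity Diagnosis-Related Group
(MS-DRG). Assignment is multi-class — one code per stay, unlike the
multi-label ICD coding problem — and is traditionally done manually by
coding specialists after discharge. `drgkit` implements the full
workflow for predicting the MS-DRG directly from the free-text narrative
of a discharge summary: catalog modeling, cross-version harmonization,
corpus preparation, two classification formulations over a pluggable
text backbone, and a bootstrap evaluation harness.

## The MS-DRG catalog and its dissection

An MS-DRG code is a *base DRG* (the principal diagnosis for medical
cases, the principal procedure for surgical ones) plus a severity
qualifier driven by secondary diagnoses: CC (complication or
comorbidity) or MCC (major CC). A base-DRG *family* carries one of four
split structures, and in the v34.0 definitions the census is:

| split type | members | families |
|---|---|---|
| three-way | with MCC / with CC / without CC/MCC | 154 |
| two-way, CC/MCC vs none | with CC/MCC / without CC/MCC | 44 |
| two-way, MCC vs rest | with MCC / without MCC | 65 |
| no split | (single code) | 77 |

The counting identity `3*154 + 2*44 + 2*65 + 77 = 757` codes over
`154 + 44 + 65 + 77 = 340` base labels is enforced by
`drg_catalog()`/`split_census()`, and `generate_catalog()` reproduces it
structurally under the default generator configuration.

`dissect()` assigns every code a base-DRG index (lexicographic in the
base title), a DRG index (ascending code number) and one of five CC/MCC
training labels, in the fixed order *without CC/MCC, with CC, with MCC,
without MCC, not applicable* (integer codes 0–4). Two assignments are
not dictated by the title grammar and are package design choices:

* **Unsplit codes train as "not applicable".** A stay coded to an
  unsplit DRG may well have a CC or MCC clinically; the label only says
  the catalog does not record it. Assigning "without CC/MCC" instead
  would be affirmatively wrong more often. This makes the CC/MCC label
  intrinsically noisy for unsplit families — a property the synthetic
  generator can reproduce via `severity_cue_strength < 1`.
* **Two-way "with CC/MCC" codes train as "with CC".** The five-label
  scheme has no two-way member; "with CC" is the minimal severity
  consistent with the title, and the inference mapping sends both
  "with CC" and "with MCC" back to the same code, so the dissect →
  infer round trip is exact.

## The inference mapping rule

Given a predicted base DRG and CC/MCC label, `infer_drg()` resolves a
final code. A label carried directly by the family resolves to that
member. Otherwise the fallback is split-specific (`drg_mapping_table()`
exports the full 20-row rule for audit): an unsplit family accepts any
label; a two-way MCC-vs-rest family sends everything but "with MCC" to
its "without MCC" code; a two-way CC/MCC-vs-none family sends "with CC"
and "with MCC" to the "with CC/MCC" code and the rest to "without
CC/MCC"; a three-way family sends "without MCC" and "not applicable" to
its least severe member. The three-way fallback is the one genuinely
open choice: "without MCC" asserts only the absence of an MCC, and in
the absence of positive CC evidence we resolve to the least severe
code. The mapping is total — every (base, label) pair yields a code —
and the round-trip identity (dissect then infer recovers every catalog
code) holds for all four split types by construction and is
property-tested over randomly generated catalogs.

## Version harmonization

CMS adjusts MS-DRG definitions annually, so a multi-year cohort carries
codes from several versions. `harmonize_records()` consolidates titles
to one target catalog in a fixed order: normalize → exact title match →
manual conversion table → fuzzy match → exclude.

* `normalize_title()` uppercases, collapses whitespace and expands
  abbreviations on word boundaries only: `W/O → WITHOUT`, `W → WITH`,
  `CATH → CATHETERIZATION`, `PROC → PROCEDURES`. Whole-token `W` is
  included because CMS itself renders severity suffixes as "W MCC" /
  "W/O CC/MCC"; substitutions inside longer tokens are never made.
* The fuzzy score is a token-set Levenshtein ratio on a 0–100 scale
  with one deliberate deviation from the textbook construction: the
  textbook token-set ratio scores 100 whenever one title's token set
  contains the other's (e.g. a retired "… WITH CC" split against its
  surviving base title), which would make 100 ambiguous. `drgkit` caps
  non-identical titles at 99, so a score of 100 certifies exact
  equality after normalization.
* The default acceptance threshold is 95 with a unique-top requirement.
  The bar is deliberately high: in the reference workflow fuzzy
  matching only *flagged* candidates for physician review, and the
  manual map (`manual_map()`, action `map` or `exclude`) is the
  faithful representation of that review. Ties at the top route to the
  manual map, and records resolving nowhere are excluded from the
  cohort — the fate of historical codes with no appropriate target.

`filter_rare()` then drops DRG labels with fewer than 2 occurrences so
every retained class can contribute to both training and testing.

## Corpus preparation

* `extract_bhc()` pulls the "brief hospital course" section — the
  narrative recounting the stay — between its header and the next
  section header (a short title line ending in a colon); an absent or
  empty section disqualifies the record. The exact boundary grammar of
  real notes varies; the packaged pattern covers the common layout and
  is the place to extend for local formats.
* `quality_filter()` drops missing sections, sections under 40
  whitespace-delimited words (read literally: exactly 40 words is
  kept), and exact duplicates of an earlier record (first occurrence
  wins). Duplication is exact string equality — no similarity
  threshold is implied by "duplicated content", so none is invented.
* `stratified_split()` allocates `round(n_c * 0.1)` test records per
  class with a seeded generator, never leaving a class without a
  training record. Small classes (2 records at a 10% fraction) land
  entirely in training, which is why a test set can carry fewer
  distinct labels than its training set.
* `tokenize_truncate()` keeps the **head** of the note when truncating.
  The hospital-course narrative opens with the presenting problem, so
  the head is the information-dense end; whether tail truncation would
  do better is an open empirical question flagged as a limitation.

## Classification formulations

Let `K` be the token sequence of the narrative and let the backbone
return one embedding per token. Because the reference setting is a
causal (decoder-only) model, classification uses the **last token's
embedding** only, mapped through a linear head to raw logits
(`logits_last_token()`).

* **Single-label**: one softmax over all C DRG codes, trained with
  categorical cross-entropy (`single_label_loss()`).
* **Two-label**: one joint head of dimension B + 5 (base block first),
  trained with `two_label_loss()` = base cross-entropy + λ · CC/MCC
  cross-entropy, λ = ½ by default. At inference the two blocks are
  argmaxed independently (ties to the lowest index) and mapped through
  `infer_drg()` (`predict_two()`). Final-DRG accuracy can never exceed
  base accuracy, since a wrong base cannot map to the right code.

### Reference backbones

Two small, fully deterministic backbones make the pipeline executable
on a laptop CPU:

* `linear_backbone()` — token vectors are one-hot, the per-token
  embedding is their running sum, so the last-token embedding is the
  sequence's token-count vector and training the head is multinomial
  logistic regression on token counts.
* `attention_backbone()` — one block of single-head causal
  self-attention (width ≤ 64) with learned token and position
  embeddings. It exists to exercise true last-token semantics and the
  adapter contract, not to compete.

### Low-rank adapter contract

`apply_adapters()` implements the low-rank adaptation convention on the
four attention projections: each frozen weight `W0` (d × k) becomes
`W0 + (alpha/r) B A` with `B` (d × r) zero-initialized and `A` (r × k)
Gaussian, so the adapted forward pass equals the base model's exactly
at initialization; only the factors are marked trainable. Defaults
r = 8, alpha = 16, dropout = 0.05 follow the reference fine-tuning
protocol (the dropout rate applies to the adapter path during adapter
training; the desk-scale head-only trainer does not reach it).

### Training

`train()` runs mini-batch AdamW (decoupled weight decay, applied to
head weights but not biases) on the cached last-token features; the
head is the trainable surface of both reference backbones. The
`train_config()` defaults — learning rate 2e-5, weight decay 0.01,
3 epochs, batch size 4, λ = ½ — are the reference LLM fine-tuning
values. A from-scratch linear model needs a from-scratch step size, so
the desk-scale experiments in the tests and the acceptance script pass
`learning_rate = 1e-2` while keeping the other defaults; this is a
property of the reference backbone, not a tuning of any evaluation
threshold.

## Evaluation

`evaluate_single()` / `evaluate_two_label()` report top-1/5/10
accuracy, macro/micro F1 and macro/micro one-vs-rest AUC, each with a
bootstrap standard deviation over 30 resamples of the full test set
drawn with replacement (sample SD, denominator n−1, seeded). Scoring
conventions, chosen where the field has no single standard:

* In single-label multi-class scoring over all classes, micro-F1
  equals top-1 accuracy (every error is one FP plus one FN); this
  identity is property-tested.
* Macro averages run over classes present in the test set (a real test
  split carries fewer labels than training); per-class F1 with a zero
  denominator scores 0; AUC uses midrank tie handling, and a class
  without both positives and negatives is skipped from the macro mean
  with a warning.
* `per_class_report()` emits per-DRG top-5 accuracy with training-case
  counts and an accuracy-banded summary (default band edges 0.2/0.8)
  for frequency-vs-performance analysis; smoothing-spline fits of that
  relationship are left to external tooling.

## The synthetic generator

`generate_catalog()`, `generate_corpus()` and
`generate_legacy_titles()` produce data with the statistical structure
the method assumes, so that every stage is testable without access to
any clinical dataset:

* family counts apportioned to the four split types (defaults in the
  154:44:65:77 ratio, hence 757 codes at 340 families);
* a Zipf class-frequency law over codes (`zipf_exponent`, default 1.1)
  emulating the long-tailed, imbalanced case distribution of real DRG
  cohorts — the tail shape is configurable since no distributional
  form is canonical;
* notes with a "Brief Hospital Course" header, base-specific keyword
  tokens, severity cue words truthful with probability
  `severity_cue_strength` (default 0.9; 1 = noiseless, mirroring the
  fact that CC/MCC labels of unsplit DRGs are inherently noisy), and
  filler vocabulary padding every narrative to at least 40 words;
* optional injected short and duplicate records with bookkeeping flags,
  so the quality filter can be checked against exact ground truth;
* legacy titles perturbed by abbreviation inversion and case changes
  (recoverable via normalization) plus a configurable fraction of
  titles from retired base-DRG families, which have no valid target
  and must be excluded. Retired families were chosen as the unmappable
  class because a severity variant added to a surviving family is
  often *correctly* fuzzy-mapped to that family rather than excluded,
  so it makes an ill-posed ground truth.

What the generator does **not** emulate: clinical prose (text is
statistically, not medically, faithful), correlated comorbidity
structure across stays, inter-author style variation, OCR or template
noise, and the sheer label count and document length of a real cohort.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated signal model — not clinical-grade
accuracy, which depends on a real corpus and a large fine-tuned
backbone.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at desk
scale: 20 base families (≈45 codes), 2,000 notes, a 4,096-slot hashing
vocabulary, 512-token truncation, 3 training epochs — sizes chosen so a
complete run takes well under a minute on one CPU while leaving every
class with enough test records to score. Softmax and cross-entropy are
computed with max-shifting; argmax and ranking ties break to the lowest
index; all randomness flows through per-call seeded generators isolated
from the session RNG, so identical seeds give byte-identical splits,
bootstrap draws and fits.

## Known limitations

* The real MS-DRG grouper logic (ICD-driven assignment rules) is out
  of scope; predictions come from text alone.
* Discharge summaries exist only after discharge; early prediction
  from admission notes is an extension point, not a feature.
* The reference backbones establish the contract and the pipeline's
  correctness; reproducing published large-model accuracies requires a
  real LLM backbone behind the same generics plus credentialed data
  access.
* The brief-hospital-course boundary grammar and the abbreviation
  table are deliberately conservative and may need extension for other
  institutions' note formats.
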