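# drgkit

Tools for predicting Medicare Severity Diagnosis-Related Groups
(MS-DRGs) from the free text of hospital discharge summaries, for
health-informatics researchers and hospital-operations teams working on
automated coding support.

Every inpatient stay billed under the U.S. prospective payment system
receives exactly one MS-DRG — a multi-class problem, unlike multi-label
ICD coding. An MS-DRG code decomposes into a **base DRG** (principal
diagnosis or procedure) and a **CC/MCC severity qualifier**
(complication/comorbidity or major CC), and each base-DRG family is
split three ways, two ways, or not at all. `drgkit` implements the full
prediction workflow around that structure:

* **catalog** — parse and validate a versioned MS-DRG catalog; dissect
  every code into base DRG + one of five CC/MCC labels ("without
  CC/MCC", "with CC", "with MCC", "without MCC", "not applicable");
  classify split families; and invert the dissection with a total
  mapping rule (`infer_drg()`) that resolves any (base, severity)
  prediction to a final code.
* **harmonize** — consolidate codes assigned under different annual
  MS-DRG versions to one target catalog: title normalization with a
  word-boundary abbreviation table, exact matching, a manual
  conversion table for physician-reviewed cases, capped token-set
  fuzzy matching with a conservative threshold, and exclusion of
  unmappable historical codes.
* **corpus** — extract the "brief hospital course" section, drop
  low-quality notes (missing, under 40 words, duplicated), split
  train/test 90/10 stratified by DRG, tokenize with a hashing
  tokenizer and head truncation.
* **model** — last-token-pooled classification over a pluggable
  backbone: single-label softmax over all codes with categorical
  cross-entropy, or a two-label head (base block + 5 CC/MCC logits)
  with combined loss `L_base + λ·L_cc` (λ = ½) and dual-argmax
  inference mapped through the catalog rule. Includes a low-rank
  adapter contract (`W0 + (alpha/r)·B·A` on the attention weights,
  exact identity at initialization), an AdamW trainer, and two small
  deterministic reference backbones.
* **evaluate** — ACC@1/5/10, macro/micro F1, macro/micro one-vs-rest
  AUC (midrank ties), bootstrap standard deviations (30 resamples of
  the full test set with replacement), and per-class
  frequency-vs-accuracy reports.
* **synthetic** — generators for catalogs (realistic split-family
  census: 154/44/65/77 at 340 families, hence 757 codes), long-tailed
  Zipf corpora with keyword-linked base signal and lexical severity
  cues, and legacy-title perturbations with exact truth maps.

See `vignettes/drg-prediction-methods.Rmd` for the model, the mapping
rule, every tunable parameter, and the generator's scope.

## Worked example

Generate a synthetic cohort (20 base families, 2,000 notes, severity
cues truthful 85% of the time), prepare it, train the two-label linear
reference backbone, and evaluate:

```r
library(drgkit)

cfg <- generator_config(n_base_families = 20, n_records = 2000,
                        severity_cue_strength = 0.85, seed = 3)
catalog <- dissect(generate_catalog(cfg))
corpus <- generate_corpus(catalog, cfg)
corpus$bhc_text <- extract_bhc(corpus$text)
corpus <- filter_rare(quality_filter(corpus)$records, 2)$records
split <- stratified_split(corpus, 0.1, seed = 4)

tok <- hash_tokenizer(4096)
dtrain <- make_dataset(split$train, catalog, tok, 512)
dtest  <- make_dataset(split$test,  catalog, tok, 512)

B <- nrow(catalog$families)
fit <- train(linear_backbone(4096, B + 5L), dtrain,
             train_config(learning_rate = 1e-2, seed = 5),
             mode = "two_label", n_base = B)
report <- evaluate_two_label(predict_logits(fit$backbone, dtest),
                             dtest$base_index, dtest$cc_index,
                             dtest$code, catalog, seed = 6)
report
```

```
Two-label evaluation over 201 records
Base DRG block:
    metric value      sd
      acc1 1.000 (0.000)
      acc5 1.000 (0.000)
     acc10 1.000 (0.000)
  macro_f1 1.000 (0.000)
  micro_f1 1.000 (0.000)
 macro_auc 1.000 (0.000)
 micro_auc 1.000 (0.000)
CC/MCC block:
    metric value      sd
      acc1 0.836 (0.023)
  macro_f1 0.841 (0.030)
  micro_f1 0.836 (0.022)
 macro_auc 0.954 (0.011)
 micro_auc 0.960 (0.009)
Final DRG ACC@1: 0.841 (0.029)
```

Reading the output: the base DRG is fully recoverable from the keyword
signal, while the deliberately noisy severity cues cap CC/MCC accuracy
near the cue truthfulness rate. Final-DRG accuracy (after the mapping
rule) sits slightly **above** raw CC/MCC accuracy because the rule
absorbs severity errors wherever the family's split cannot express
them — unsplit families accept any severity prediction. Parenthesized
values are bootstrap standard deviations.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/drgkit.R simulate  --out data/ --families 40 --records 2000 --seed 1
Rscript inst/cli/drgkit.R catalog   --catalog data/catalog.tsv --dissect-out data/dissection.tsv
Rscript inst/cli/drgkit.R harmonize --notes data/notes.csv --catalog data/catalog.tsv --out data/harmonized.csv
Rscript inst/cli/drgkit.R prepare   --notes data/notes.csv --catalog data/catalog.tsv --out-dir data/prepared --seed 1
```

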