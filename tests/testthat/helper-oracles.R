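# Fixtures and independent oracles shared across the test files.  The
# oracles deliberately use different code paths (direct formula
# evaluation, O(n^2) pair counting, exhaustive tallies) from the package
# implementations they check.

# A small hand-written catalog covering all four split types, including
# the classic unsplit DRG 69 and the two-way MCC-vs-rest 56/57 pair.
fixture_catalog <- function() {
  drg_catalog(data.frame(
    code = c(69, 56, 57, 52, 53, 48, 49, 50),
    title = c(
      "TRANSIENT ISCHEMIA",
      "DEGENERATIVE NERVOUS SYSTEM DISORDERS WITH MCC",
      "DEGENERATIVE NERVOUS SYSTEM DISORDERS WITHOUT MCC",
      "SPINAL DISORDERS AND INJURIES WITH CC/MCC",
      "SPINAL DISORDERS AND INJURIES WITHOUT CC/MCC",
      "KIDNEY AND URINARY TRACT INFECTIONS WITH MCC",
      "KIDNEY AND URINARY TRACT INFECTIONS WITH CC",
      "KIDNEY AND URINARY TRACT INFECTIONS WITHOUT CC/MCC"
    ),
    stringsAsFactors = FALSE
  ))
}

# Independent inference oracle: recomputes the final code from a family's
# member suffixes with direct if/else logic (no lookup table).
oracle_infer <- function(family_codes, family_suffixes, cc_label) {
  pick <- function(sfx) family_codes[match(sfx, family_suffixes)]
  direct <- pick(cc_label)                      # label present in family?
  if (!is.na(direct)) return(direct)
  st <- drgkit::split_type(family_suffixes)
  if (st == "NO_SPLIT") return(family_codes[1])
  if (st == "TWO_WAY_MCC_VS_REST") return(pick("WITHOUT_MCC"))
  if (st == "TWO_WAY_CCMCC_VS_NONE") {
    if (cc_label %in% c("WITH_CC", "WITH_MCC")) return(pick("WITH_CC_MCC"))
    return(pick("WITHOUT_CC_MCC"))
  }
  pick("WITHOUT_CC_MCC")                        # three-way fallback
}

# Direct cross-entropy evaluation (no stabilization tricks).
oracle_ce <- function(logits, target0) {
  -log(exp(logits[target0 + 1]) / sum(exp(logits)))
}

# O(n^2) concordant-pair AUC with half credit for ties.
oracle_auc_pairs <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Per-class F1 from an explicit confusion tally.
oracle_f1 <- function(pred, truth, classes) {
  f1s <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  f1s
}

# end-to-end synthetic pipeline up to model-ready splits
fixture_pipeline <- function(cfg, split_seed = 5L, vocab = 4096L,
                             max_tokens = 512L) {
  catalog <- dissect(generate_catalog(cfg))
  corp <- generate_corpus(catalog, cfg)
  corp$bhc_text <- extract_bhc(corp$text)
  corp <- quality_filter(corp)$records
  corp <- filter_rare(corp)$records
  sp <- stratified_split(corp, seed = split_seed)
  tok <- hash_tokenizer(vocab)
  list(
    catalog = catalog, split = sp, tokenizer = tok,
    train = make_dataset(sp$train, catalog, tok, max_tokens),
    test = make_dataset(sp$test, catalog, tok, max_tokens)
  )
}
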