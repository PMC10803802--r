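# Corpus preparation: extract the "brief hospital course" narrative from
# discharge summaries, filter low-quality notes, split train/test
# stratified by DRG, and tokenize for a classification backbone.

# A section header: a short title ending in ':' at the start of a line.
.section_header_pattern <-
  "\n[ \t]*[A-Za-z][A-Za-z0-9 ,'()/-]{0,80}:[ \t]*(\n|$)"

#' Extract the "brief hospital course" section from a discharge summary
#'
#' Locates a case-insensitive "Brief Hospital Course" header (with or
#' without a trailing colon) and returns the text up to the next section
#' header (a short title line ending in a colon) or the end of the
#' document.  An absent header, or a header with an empty body, yields
#' `NA`.
#'
#' @param raw_text character vector of full discharge-summary texts.
#' @return Character vector of extracted sections (`NA` where absent).
#' @export
extract_bhc <- function(raw_text) {
  vapply(raw_text, function(txt) {
    if (is.na(txt)) return(NA_character_)
    m <- regexpr("brief hospital course[ \t]*:?[ \t]*\n?", txt,
                 ignore.case = TRUE)
    if (m == -1) return(NA_character_)
    body <- substring(txt, m + attr(m, "match.length"))
    nxt <- regexpr(.section_header_pattern, paste0("\n", body))
    if (nxt != -1) body <- substring(body, 1, nxt - 1)
    body <- trimws(body)
    if (!nzchar(body)) NA_character_ else body
  }, character(1), USE.NAMES = FALSE)
}

#' Count whitespace-delimited words
#'
#' @param text character vector.
#' @return Integer vector of token counts (0 for `NA` or empty text).
#' @export
count_words <- function(text) {
  vapply(text, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(0L)
    length(strsplit(trimws(x), "[[:space:]]+")[[1]])
  }, integer(1), USE.NAMES = FALSE)
}

#' Quality-filter stay records
#'
#' Drops records whose extracted narrative is missing, shorter than
#' `min_words` whitespace-delimited words, or an exact duplicate of an
#' earlier record's narrative (first occurrence kept, document order).
#' "Less than `min_words` words" is read literally: a record with exactly
#' `min_words` words is kept.  Idempotent.
#'
#' @param records data.frame with a `bhc_text` column.
#' @param min_words minimum word count (default 40).
#' @return List with `records` (kept rows), `dropped` (dropped rows with a
#'   `drop_reason` column: "missing", "short" or "duplicate"; the first
#'   applicable reason in that order is recorded) and `counts` per reason.
#' @export
quality_filter <- function(records, min_words = 40L) {
  if (!"bhc_text" %in% names(records)) {
    stop("records must carry a 'bhc_text' column")
  }
  wc <- count_words(records$bhc_text)
  missing <- is.na(records$bhc_text) | !nzchar(trimws(records$bhc_text))
  short <- !missing & wc < min_words
  dup <- !missing & duplicated(records$bhc_text)
  reason <- rep(NA_character_, nrow(records))
  reason[dup] <- "duplicate"
  reason[short] <- "short"
  reason[missing] <- "missing"
  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  kept$word_count <- wc[keep]
  rownames(kept) <- NULL
  dropped <- records[!keep, , drop = FALSE]
  dropped$drop_reason <- reason[!keep]
  rownames(dropped) <- NULL
  counts <- table(factor(reason[!keep],
                         levels = c("missing", "short", "duplicate")))
  list(records = kept, dropped = dropped, counts = counts)
}

#' Stratified train/test split
#'
#' Allocates `round(n_c * test_fraction)` test records within each DRG
#' class (never more than `n_c - 1`, so every class with at least two
#' records keeps at least one training record), sampling within class
#' with a seeded generator.  Classes too small to fund a test record
#' (e.g. two records at a 10% test fraction) go entirely to training,
#' which is why the test set can carry fewer distinct labels than the
#' training set.
#'
#' @param records data.frame with a `code` column.
#' @param test_fraction test share in (0, 1); default 0.1.
#' @param seed integer seed; the split is byte-identical given the same
#'   seed.
#' @return List with `train`, `test` (row subsets), `seed` and
#'   `stratification` (per-code train/test counts).
#' @export
stratified_split <- function(records, test_fraction = 0.1, seed = 1L) {
  if (!"code" %in% names(records)) stop("records must carry a 'code' column")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie in (0, 1)")
  }
  rng <- .seeded_rng(seed)
  idx_by_code <- split(seq_len(nrow(records)), records$code)
  test_idx <- integer(0)
  for (ix in idx_by_code) {
    n_test <- min(round(length(ix) * test_fraction), length(ix) - 1L)
    if (n_test > 0) test_idx <- c(test_idx, rng$sample(ix, n_test))
  }
  test_idx <- sort(test_idx)
  is_test <- seq_len(nrow(records)) %in% test_idx
  train <- records[!is_test, , drop = FALSE]
  test <- records[is_test, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  strat <- merge(
    as.data.frame(table(code = train$code), responseName = "n_train"),
    as.data.frame(table(code = test$code), responseName = "n_test"),
    by = "code", all = TRUE
  )
  strat[is.na(strat)] <- 0L
  list(train = train, test = test, seed = seed, stratification = strat)
}

#' Hashing tokenizer
#'
#' The reference tokenizer for the desk-scale backbones: lowercases,
#' splits on non-alphanumeric characters and hashes each token into a
#' fixed-size vocabulary with a polynomial rolling hash.  Real LLM
#' tokenizers are supplied by a backbone adapter, not reimplemented here.
#'
#' @param vocab_size vocabulary size (default 2^15).
#' @return An object of class `hash_tokenizer`.
#' @export
hash_tokenizer <- function(vocab_size = 32768L) {
  stopifnot(vocab_size >= 2)
  structure(list(vocab_size = as.integer(vocab_size)),
            class = "hash_tokenizer")
}

# polynomial rolling hash, base 31, modular in double precision (all
# intermediates < 2^53 for vocab sizes up to 2^26)
.hash_token <- function(token, vocab_size) {
  h <- 0
  for (cc in utf8ToInt(token)) h <- (h * 31 + cc) %% vocab_size
  as.integer(h)
}

#' Tokenize text and truncate to a maximum length
#'
#' Token ids are 1-based indices into the tokenizer's vocabulary.
#' Truncation keeps the first `max_tokens` tokens — the head of a
#' hospital-course narrative opens with the presenting problem — and is
#' idempotent.
#'
#' @param text character scalar (non-empty).
#' @param tokenizer a `hash_tokenizer`.
#' @param max_tokens maximum sequence length (default 512).
#' @return Integer vector of token ids, length in \[1, max_tokens\].
#' @export
tokenize_truncate <- function(text, tokenizer = hash_tokenizer(),
                              max_tokens = 512L) {
  stopifnot(inherits(tokenizer, "hash_tokenizer"), max_tokens >= 1)
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    stop("text must be a single non-empty string")
  }
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("text contains no alphanumeric tokens")
  toks <- utils::head(toks, max_tokens)
  vapply(toks, .hash_token, integer(1),
         vocab_size = tokenizer$vocab_size, USE.NAMES = FALSE) + 1L
}

#' Read a stay table from CSV/TSV/JSONL
#'
#' @param path input file; format inferred from the extension.  Expected
#'   columns/fields: `stay_id`, `text`, `drg_title` (or `drg_code`),
#'   `drg_version`.
#' @return data.frame of stay records.
#' @export
read_stays <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    rows <- lapply(readLines(path), jsonlite::fromJSON)
    return(do.call(rbind, lapply(rows, as.data.frame,
                                 stringsAsFactors = FALSE)))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
}

#' Write model-ready records to JSONL
#'
#' @param records data.frame of prepared records.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_stays_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}
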