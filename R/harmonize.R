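# Harmonization of DRG codes assigned under different annual MS-DRG
# versions to one target catalog (v34.0 in the reference workflow):
# normalize -> exact title match -> manual conversion table -> fuzzy match
# above a conservative threshold -> exclude.

# Levenshtein similarity on the 0-100 scale of python-Levenshtein's
# "ratio": (l1 + l2 - d) / (l1 + l2) with substitution cost 2.
.lev_ratio <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la + lb == 0) return(100)
  d <- utils::adist(a, b, costs = c(insertions = 1, deletions = 1,
                                    substitutions = 2))[1, 1]
  100 * (la + lb - d) / (la + lb)
}

#' Token-set similarity between two titles
#'
#' Token-based edit similarity on a 0--100 scale: both titles are split
#' into whitespace tokens; the sorted token intersection and the sorted
#' full token sets are compared pairwise by Levenshtein ratio and the best
#' of the three comparisons is taken (the "token set ratio" construction).
#' Because a strict subset of tokens would otherwise score 100, the score
#' of two non-identical titles is capped at 99: a score of 100 certifies
#' exact equality.
#'
#' @param a,b character scalars (normalized titles).
#' @return Numeric similarity in \[0, 100\].
#' @export
token_set_ratio <- function(a, b) {
  if (identical(a, b)) return(100)
  ta <- sort(unique(strsplit(a, "[[:space:]]+")[[1]]))
  tb <- sort(unique(strsplit(b, "[[:space:]]+")[[1]]))
  inter <- intersect(ta, tb)
  s_int <- paste(inter, collapse = " ")
  s_a   <- paste(c(inter, setdiff(ta, tb)), collapse = " ")
  s_b   <- paste(c(inter, setdiff(tb, ta)), collapse = " ")
  score <- max(.lev_ratio(s_int, s_a),
               .lev_ratio(s_int, s_b),
               .lev_ratio(s_a, s_b))
  min(score, 99)
}

#' Rank catalog codes by fuzzy similarity to a title
#'
#' @param title a normalized title (see [normalize_title()]).
#' @param catalog a `drg_catalog` to match against.
#' @param k number of candidates to return.
#' @return data.frame with columns `code`, `title`, `score` (0--100,
#'   100 iff exact normalized match) and `method` ("exact" or "fuzzy"),
#'   ordered by descending score with ties broken by ascending code.
#' @export
fuzzy_candidates <- function(title, catalog, k = 5L) {
  stopifnot(inherits(catalog, "drg_catalog"))
  if (nrow(catalog$codes) == 0) stop("empty catalog")
  tab <- catalog$codes
  score <- vapply(tab$title, token_set_ratio, numeric(1), a = title)
  ord <- order(-score, tab$code)
  top <- utils::head(ord, k)
  data.frame(
    code = tab$code[top], title = tab$title[top],
    score = unname(score[top]),
    method = ifelse(score[top] == 100, "exact", "fuzzy"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a manual harmonization map
#'
#' @param path CSV with columns `source_title`, `target_code`, `action`
#'   ("map" or "exclude") and optional `note`.  Source titles are
#'   normalized on load.
#' @param catalog target catalog; every mapped target code must exist in
#'   it (rejected at load otherwise).
#' @return data.frame of class `harmonization_map`.
#' @export
read_manual_map <- function(path, catalog) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  manual_map(tab, catalog)
}

#' @rdname read_manual_map
#' @param entries data.frame with the same columns as the CSV.
#' @export
manual_map <- function(entries, catalog) {
  stopifnot(inherits(catalog, "drg_catalog"))
  need <- c("source_title", "target_code", "action")
  if (!all(need %in% names(entries))) {
    stop("manual map needs columns: ", paste(need, collapse = ", "))
  }
  entries$source_title <- normalize_title(entries$source_title)
  if (anyDuplicated(entries$source_title)) {
    stop("manual map assigns a source title twice: ",
         paste(unique(entries$source_title[duplicated(entries$source_title)]),
               collapse = ", "))
  }
  bad_action <- setdiff(entries$action, c("map", "exclude"))
  if (length(bad_action)) stop("unknown action(s): ",
                               paste(bad_action, collapse = ", "))
  mapped <- entries$action == "map"
  entries$target_code <- suppressWarnings(as.integer(entries$target_code))
  if (any(mapped & is.na(entries$target_code))) {
    stop("action 'map' entries must carry an integer target_code")
  }
  missing <- setdiff(entries$target_code[mapped], catalog$codes$code)
  if (length(missing)) {
    stop("manual map targets absent from catalog: ",
         paste(missing, collapse = ", "))
  }
  class(entries) <- c("harmonization_map", class(entries))
  entries
}

#' Empty manual map
#' @param catalog target catalog.
#' @return A `harmonization_map` with zero entries.
#' @export
empty_manual_map <- function(catalog) {
  manual_map(data.frame(source_title = character(0),
                        target_code = integer(0),
                        action = character(0),
                        stringsAsFactors = FALSE), catalog)
}

#' Harmonize stay records to a target catalog
#'
#' For each record's DRG title: normalize; accept an exact title match in
#' the target catalog (`EXACT`); otherwise consult the manual map
#' (`MANUAL` or `EXCLUDED` per its action); otherwise accept the top fuzzy
#' candidate iff its score reaches `threshold` and it is the unique top
#' scorer (`FUZZY_ACCEPTED`); otherwise exclude (`EXCLUDED`).  Excluded
#' stays are dropped from the harmonized output, mirroring cohort
#' construction in which unmappable historical codes are removed.
#'
#' @param records data.frame with a `drg_title` column (plus any other
#'   columns, carried through).
#' @param catalog the target `drg_catalog`.
#' @param manual a `harmonization_map` (default: empty).
#' @param threshold fuzzy acceptance threshold on the 0--100 scale
#'   (default 95; high on purpose — the reference workflow used fuzzy
#'   matching only to flag candidates for physician review).
#' @return List with `records` (kept rows, with `code` and `provenance`
#'   columns added and titles replaced by the matched catalog title),
#'   `report` (per-record disposition, same row count as the input) and
#'   `counts` (records per provenance).
#' @export
harmonize_records <- function(records, catalog,
                              manual = empty_manual_map(catalog),
                              threshold = 95) {
  stopifnot(inherits(catalog, "drg_catalog"))
  if (!inherits(manual, "harmonization_map")) {
    stop("manual must be a harmonization_map (see manual_map())")
  }
  if (!"drg_title" %in% names(records)) {
    stop("records must carry a 'drg_title' column")
  }
  titles <- normalize_title(records$drg_title)
  cat_code <- stats::setNames(catalog$codes$code, catalog$codes$title)

  n <- length(titles)
  code <- rep(NA_integer_, n)
  provenance <- character(n)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tt <- titles[i]
    if (!is.na(cat_code[tt])) {
      code[i] <- cat_code[[tt]]; provenance[i] <- "EXACT"; score[i] <- 100
      next
    }
    mi <- match(tt, manual$source_title)
    if (!is.na(mi)) {
      if (manual$action[mi] == "map") {
        code[i] <- manual$target_code[mi]; provenance[i] <- "MANUAL"
      } else {
        provenance[i] <- "EXCLUDED"
      }
      next
    }
    cand <- fuzzy_candidates(tt, catalog, k = 2L)
    score[i] <- cand$score[1]
    unique_top <- nrow(cand) < 2 || cand$score[1] > cand$score[2]
    if (cand$score[1] >= threshold && unique_top) {
      code[i] <- cand$code[1]; provenance[i] <- "FUZZY_ACCEPTED"
    } else {
      provenance[i] <- "EXCLUDED"
    }
  }

  report <- data.frame(
    row = seq_len(n), source_title = titles, code = code,
    provenance = provenance, top_score = score,
    stringsAsFactors = FALSE
  )
  kept <- records[!is.na(code), , drop = FALSE]
  kept$code <- code[!is.na(code)]
  kept$drg_title <- catalog$codes$title[match(kept$code, catalog$codes$code)]
  kept$provenance <- provenance[!is.na(code)]
  rownames(kept) <- NULL
  counts <- table(factor(provenance, levels = c("EXACT", "MANUAL",
                                                "FUZZY_ACCEPTED",
                                                "EXCLUDED")))
  list(records = kept, report = report, counts = counts)
}

#' Drop rare DRG labels
#'
#' Removes records whose DRG label occurs fewer than `min_count` times,
#' the rare-class filter applied after harmonization so every retained
#' class can contribute to both training and testing.
#'
#' @param records data.frame with a `code` column.
#' @param min_count minimum occurrences a label needs to survive
#'   (default 2).
#' @return List with `records` (kept rows) and `dropped_labels` (codes
#'   removed, with their counts).
#' @export
filter_rare <- function(records, min_count = 2L) {
  if (!"code" %in% names(records)) stop("records must carry a 'code' column")
  counts <- table(records$code)
  rare <- names(counts)[counts < min_count]
  keep <- !(as.character(records$code) %in% rare)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       dropped_labels = data.frame(code = as.integer(rare),
                                   count = as.integer(counts[rare]),
                                   stringsAsFactors = FALSE))
}
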