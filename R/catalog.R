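# MS-DRG catalog model: title normalization, severity-suffix parsing,
# dissection into base DRG + CC/MCC, split-family classification, and the
# inverse mapping rule used to reassemble a final DRG from the two parts.

#' CC/MCC training labels
#'
#' The five severity labels a hospital stay can carry after dissection of
#' its DRG code: "without CC/MCC", "with CC", "with MCC", "without MCC" and
#' "not applicable".  Their order is fixed so that integer indices 0--4 are
#' stable across runs and match the order used by the two-label classifier
#' head.
#'
#' @return Character vector of length 5; `cc_index()` maps a label to its
#'   0-based integer code and `cc_label_from_index()` inverts it.
#' @export
cc_labels <- function() {
  c("WITHOUT_CC_MCC", "WITH_CC", "WITH_MCC", "WITHOUT_MCC", "NOT_APPLICABLE")
}

#' @rdname cc_labels
#' @param label character vector of CC/MCC labels.
#' @export
cc_index <- function(label) {
  idx <- match(label, cc_labels())
  if (anyNA(idx)) {
    stop("unknown CC/MCC label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' @rdname cc_labels
#' @param index integer vector in 0..4.
#' @export
cc_label_from_index <- function(index) {
  if (any(index < 0L | index > 4L)) stop("CC/MCC index out of range 0..4")
  cc_labels()[index + 1L]
}

#' Catalog-side severity suffixes
#'
#' The suffix vocabulary found in MS-DRG titles.  `WITH_CC_MCC` ("... with
#' CC/MCC") appears only on catalog codes of two-way split families and is
#' deliberately not a member of the five CC/MCC training labels.
#'
#' @return Character vector of the six recognized suffixes.
#' @export
catalog_suffixes <- function() {
  c("WITH_MCC", "WITH_CC", "WITHOUT_CC_MCC", "WITHOUT_MCC",
    "WITH_CC_MCC", "NONE")
}

#' Split-family types
#'
#' @return Character vector of the four family types: three-way split,
#'   two-way "with CC/MCC vs without", two-way "with MCC vs without MCC",
#'   and unsplit.
#' @export
split_types <- function() {
  c("THREE_WAY", "TWO_WAY_CCMCC_VS_NONE", "TWO_WAY_MCC_VS_REST", "NO_SPLIT")
}

# Canonical suffix set for each split type (order-insensitive comparison).
.split_suffix_sets <- list(
  THREE_WAY             = c("WITH_MCC", "WITH_CC", "WITHOUT_CC_MCC"),
  TWO_WAY_CCMCC_VS_NONE = c("WITH_CC_MCC", "WITHOUT_CC_MCC"),
  TWO_WAY_MCC_VS_REST   = c("WITH_MCC", "WITHOUT_MCC"),
  NO_SPLIT              = "NONE"
)

# Rendering of each suffix as it appears at the end of a normalized title.
.suffix_rendering <- c(
  WITH_MCC       = "WITH MCC",
  WITH_CC        = "WITH CC",
  WITHOUT_CC_MCC = "WITHOUT CC/MCC",
  WITHOUT_MCC    = "WITHOUT MCC",
  WITH_CC_MCC    = "WITH CC/MCC",
  NONE           = ""
)

#' Abbreviation substitution table
#'
#' Whole-token substitutions applied by [normalize_title()].  Ships the
#' printed MS-DRG conventions (W/O, CATH, PROC) plus whole-token W, which
#' CMS uses for "with" in severity suffixes ("... W MCC").  Substitutions
#' are applied on word boundaries only, so tokens merely containing these
#' strings are never touched.
#'
#' @return Named character vector: names are abbreviations, values their
#'   expansions.
#' @export
drg_abbreviations <- function() {
  c("W/O"  = "WITHOUT",
    "W"    = "WITH",
    "CATH" = "CATHETERIZATION",
    "PROC" = "PROCEDURES")
}

#' Normalize a DRG title
#'
#' Uppercases, expands abbreviations on word boundaries per
#' [drg_abbreviations()], and collapses internal whitespace.  Idempotent:
#' normalizing a normalized title is the identity.
#'
#' @param title character vector of titles (non-empty strings).
#' @param abbreviations named character vector of whole-token
#'   substitutions; defaults to [drg_abbreviations()].
#' @return Character vector of normalized titles.
#' @examples
#' normalize_title("Urinary Stones w/o MCC")
#' @export
normalize_title <- function(title, abbreviations = drg_abbreviations()) {
  if (any(!nzchar(title))) stop("title must be non-empty")
  out <- toupper(title)
  # longer abbreviations first so W/O is expanded before bare W
  abbreviations <- abbreviations[order(-nchar(names(abbreviations)))]
  for (i in seq_along(abbreviations)) {
    abbr <- names(abbreviations)[i]
    # \b does not sit between '/' and end-of-token; anchor on space/edges.
    # Trailing boundary is a lookahead so consecutive tokens both match.
    pat <- paste0("(^|[ ])", gsub("([^A-Z0-9 ])", "\\\\\\1", abbr),
                  "(?=$|[ ])")
    out <- gsub(pat, paste0("\\1", abbreviations[[i]]), out, perl = TRUE)
  }
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

# Trailing suffix patterns, most specific first; slashless variants accepted.
.suffix_patterns <- list(
  WITHOUT_CC_MCC = " WITHOUT CC[ /]MCC$",
  WITH_CC_MCC    = " WITH CC[ /]MCC$",
  WITHOUT_MCC    = " WITHOUT MCC$",
  WITH_MCC       = " WITH MCC$",
  WITH_CC        = " WITH CC$"
)

.strip_one_suffix <- function(title) {
  for (sfx in names(.suffix_patterns)) {
    pat <- .suffix_patterns[[sfx]]
    if (grepl(pat, title)) {
      return(list(base = sub(pat, "", title), suffix = sfx))
    }
  }
  list(base = title, suffix = "NONE")
}

#' Split a normalized title into base title and severity suffix
#'
#' Recognizes the trailing severity phrases "WITH MCC", "WITH CC",
#' "WITHOUT CC/MCC", "WITHOUT MCC" and "WITH CC/MCC" (slashless variants
#' included) and strips them; a title with no such trailing phrase is its
#' own base title with suffix `NONE`.  Severity words in the middle of a
#' title are never treated as suffixes.  A title carrying two stacked
#' severity phrases is rejected as ambiguous.
#'
#' @param title character vector of already-normalized titles (see
#'   [normalize_title()]).
#' @return A data.frame with columns `base_title` and `suffix`.
#' @examples
#' parse_suffix("SPINAL DISORDERS AND INJURIES WITHOUT CC/MCC")
#' @export
parse_suffix <- function(title) {
  res <- lapply(title, function(tt) {
    first <- .strip_one_suffix(tt)
    if (first$suffix != "NONE") {
      second <- .strip_one_suffix(first$base)
      if (second$suffix != "NONE") {
        stop("ambiguous title with two severity phrases: ", sQuote(tt))
      }
    }
    first
  })
  data.frame(
    base_title = vapply(res, `[[`, character(1), "base"),
    suffix     = vapply(res, `[[`, character(1), "suffix"),
    stringsAsFactors = FALSE
  )
}

#' Classify a family's suffix set into its split type
#'
#' @param suffixes character vector of the catalog suffixes carried by one
#'   base-DRG family (order and duplication irrelevant).
#' @return One of [split_types()].  A suffix set matching none of the four
#'   canonical sets is rejected with the offending suffixes listed.
#' @examples
#' split_type(c("WITH_MCC", "WITH_CC", "WITHOUT_CC_MCC"))
#' @export
split_type <- function(suffixes) {
  if (length(suffixes) == 0) stop("empty suffix set")
  sfx <- sort(unique(suffixes))
  for (st in names(.split_suffix_sets)) {
    if (identical(sfx, sort(.split_suffix_sets[[st]]))) return(st)
  }
  stop("suffix set matches no split type: {",
       paste(sfx, collapse = ", "), "}")
}

#' Build a validated MS-DRG catalog
#'
#' Takes a table of catalog rows (code number, title, version), normalizes
#' and parses each title, groups codes into base-DRG families and verifies
#' that every family's suffix set matches one of the four split types.
#'
#' @param codes data.frame with columns `code` (integer DRG numbers,
#'   unique), `title` (character) and optionally `version` (character,
#'   recycled if scalar; default "34.0").
#' @return An object of class `drg_catalog`: a list with `codes` (one row
#'   per catalog code, with `base_title`, `suffix` and `split_type`
#'   columns added) and `families` (one row per base DRG).
#' @seealso [dissect()], [read_drg_catalog()]
#' @export
drg_catalog <- function(codes) {
  if (!is.data.frame(codes) || !all(c("code", "title") %in% names(codes))) {
    stop("codes must be a data.frame with columns 'code' and 'title'")
  }
  code_num <- as.integer(codes$code)
  if (anyNA(code_num)) stop("non-integer DRG code numbers")
  if (anyDuplicated(code_num)) {
    stop("duplicated DRG code numbers: ",
         paste(unique(code_num[duplicated(code_num)]), collapse = ", "))
  }
  version <- if ("version" %in% names(codes)) as.character(codes$version)
             else rep("34.0", length(code_num))
  version <- rep_len(version, length(code_num))
  title <- normalize_title(as.character(codes$title))
  parsed <- parse_suffix(title)

  tab <- data.frame(
    code = code_num, title = title, version = version,
    base_title = parsed$base_title, suffix = parsed$suffix,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$code), , drop = FALSE]
  rownames(tab) <- NULL

  fam_split <- vapply(
    split(tab$suffix, tab$base_title),
    function(s) {
      if (anyDuplicated(s)) {
        stop("family with repeated suffix: ", paste(s, collapse = ", "))
      }
      split_type(s)
    },
    character(1)
  )
  tab$split_type <- unname(fam_split[tab$base_title])

  families <- data.frame(
    base_title = names(fam_split),
    split_type = unname(fam_split),
    n_codes    = as.integer(table(tab$base_title)[names(fam_split)]),
    stringsAsFactors = FALSE
  )
  families <- families[order(families$base_title), , drop = FALSE]
  rownames(families) <- NULL

  structure(list(codes = tab, families = families), class = "drg_catalog")
}

#' @export
print.drg_catalog <- function(x, ...) {
  cat("MS-DRG catalog:", nrow(x$codes), "codes in", nrow(x$families),
      "base-DRG families\n")
  print(table(x$families$split_type))
  if (is_dissected(x)) {
    cat("dissected: label space C =", nrow(x$codes),
        ", B =", nrow(x$families), ", 5 CC/MCC labels\n")
  }
  invisible(x)
}

#' Census of split-family types
#'
#' @param catalog a `drg_catalog`.
#' @return Named integer vector: number of families of each split type,
#'   plus `codes` (total catalog codes) and `base` (total families).
#' @export
split_census <- function(catalog) {
  stopifnot(inherits(catalog, "drg_catalog"))
  n <- vapply(split_types(),
              function(st) sum(catalog$families$split_type == st),
              integer(1))
  c(n, codes = nrow(catalog$codes), base = nrow(catalog$families))
}

# cc training label for each catalog suffix.  WITH_CC_MCC codes train as
# WITH_CC: the five-label scheme has no two-way "with CC/MCC" member, and
# the inference mapping sends both WITH_CC and WITH_MCC back to the same
# code, so the round trip is preserved.
.suffix_to_cc <- c(
  WITH_MCC       = "WITH_MCC",
  WITH_CC        = "WITH_CC",
  WITHOUT_CC_MCC = "WITHOUT_CC_MCC",
  WITHOUT_MCC    = "WITHOUT_MCC",
  WITH_CC_MCC    = "WITH_CC",
  NONE           = "NOT_APPLICABLE"
)

#' The inference mapping table
#'
#' For each split type and each of the five predicted CC/MCC labels, the
#' catalog suffix of the family member the prediction resolves to.  Labels
#' present in the family resolve directly; labels absent from the family
#' fall back by severity logic: an unsplit family accepts any label; a
#' two-way MCC-vs-rest family sends everything but WITH_MCC to its
#' "without MCC" code; a two-way CC/MCC-vs-none family sends WITH_CC and
#' WITH_MCC to its "with CC/MCC" code and the rest to "without CC/MCC";
#' a three-way family sends WITHOUT_MCC and NOT_APPLICABLE to its least
#' severe, "without CC/MCC", code.
#'
#' @return data.frame with columns `split_type`, `cc_label`,
#'   `target_suffix` (20 rows), exportable as TSV for audit.
#' @export
drg_mapping_table <- function() {
  map <- list(
    THREE_WAY = c(WITHOUT_CC_MCC = "WITHOUT_CC_MCC",
                  WITH_CC        = "WITH_CC",
                  WITH_MCC       = "WITH_MCC",
                  WITHOUT_MCC    = "WITHOUT_CC_MCC",
                  NOT_APPLICABLE = "WITHOUT_CC_MCC"),
    TWO_WAY_CCMCC_VS_NONE = c(WITHOUT_CC_MCC = "WITHOUT_CC_MCC",
                              WITH_CC        = "WITH_CC_MCC",
                              WITH_MCC       = "WITH_CC_MCC",
                              WITHOUT_MCC    = "WITHOUT_CC_MCC",
                              NOT_APPLICABLE = "WITHOUT_CC_MCC"),
    TWO_WAY_MCC_VS_REST = c(WITHOUT_CC_MCC = "WITHOUT_MCC",
                            WITH_CC        = "WITHOUT_MCC",
                            WITH_MCC       = "WITH_MCC",
                            WITHOUT_MCC    = "WITHOUT_MCC",
                            NOT_APPLICABLE = "WITHOUT_MCC"),
    NO_SPLIT = c(WITHOUT_CC_MCC = "NONE",
                 WITH_CC        = "NONE",
                 WITH_MCC       = "NONE",
                 WITHOUT_MCC    = "NONE",
                 NOT_APPLICABLE = "NONE")
  )
  do.call(rbind, lapply(names(map), function(st) {
    data.frame(split_type = st, cc_label = names(map[[st]]),
               target_suffix = unname(map[[st]]),
               stringsAsFactors = FALSE)
  }))
}

#' Dissect a catalog into base-DRG and CC/MCC label spaces
#'
#' Assigns every catalog code its base-DRG index, its CC/MCC training
#' label and its DRG index, and precomputes the inference lookup (base
#' index x CC/MCC label -> final code).  Index order is deterministic:
#' DRG indices ascend by code number, base indices are lexicographic in
#' the base title, CC/MCC indices follow [cc_labels()].
#'
#' @param catalog a `drg_catalog`.
#' @return The catalog with components added: `dissection` (per-code
#'   data.frame with `drg_index`, `base_index`, `cc_label`), `label_space`
#'   (list `drg`, `base`, `cc` of index vectors named by code/title/label)
#'   and the inference lookup; class gains `drg_catalog_dissected`.
#' @export
dissect <- function(catalog) {
  stopifnot(inherits(catalog, "drg_catalog"))
  tab <- catalog$codes
  base_titles <- sort(catalog$families$base_title)

  dis <- data.frame(
    code       = tab$code,
    base_title = tab$base_title,
    split_type = tab$split_type,
    drg_index  = seq_len(nrow(tab)) - 1L,            # already code-sorted
    base_index = match(tab$base_title, base_titles) - 1L,
    cc_label   = unname(.suffix_to_cc[tab$suffix]),
    stringsAsFactors = FALSE
  )

  # inference lookup: B x 5 matrix of code numbers
  mtab <- drg_mapping_table()
  infer <- matrix(NA_integer_, nrow = length(base_titles), ncol = 5L,
                  dimnames = list(base_titles, cc_labels()))
  for (bi in seq_along(base_titles)) {
    fam <- tab[tab$base_title == base_titles[bi], , drop = FALSE]
    st <- fam$split_type[1]
    rows <- mtab[mtab$split_type == st, , drop = FALSE]
    target <- rows$target_suffix[match(cc_labels(), rows$cc_label)]
    infer[bi, ] <- fam$code[match(target, fam$suffix)]
  }
  if (anyNA(infer)) stop("internal error: incomplete inference table")

  catalog$dissection <- dis
  catalog$label_space <- list(
    drg  = stats::setNames(dis$drg_index, dis$code),
    base = stats::setNames(seq_along(base_titles) - 1L, base_titles),
    cc   = stats::setNames(0:4, cc_labels())
  )
  catalog$infer_table <- infer
  class(catalog) <- unique(c("drg_catalog_dissected", class(catalog)))
  catalog
}

#' @rdname dissect
#' @export
is_dissected <- function(catalog) inherits(catalog, "drg_catalog_dissected")

#' Infer a final DRG code from a base-DRG and a CC/MCC prediction
#'
#' Applies the mapping rule of [drg_mapping_table()]: a predicted CC/MCC
#' label carried by the target family resolves to that member directly;
#' otherwise the label falls back by split type.  The mapping is total:
#' every (base index, CC/MCC label) pair yields a code.
#'
#' @param base_index integer vector of base-DRG indices (0-based).
#' @param cc_label character vector of CC/MCC labels (recycled), or
#'   0-based integer indices into [cc_labels()].
#' @param catalog a dissected catalog.
#' @return Integer vector of DRG code numbers.
#' @export
infer_drg <- function(base_index, cc_label, catalog) {
  if (!is_dissected(catalog)) stop("catalog must be dissected first")
  B <- nrow(catalog$infer_table)
  if (any(base_index < 0L | base_index >= B)) {
    stop("base_index out of range 0..", B - 1L)
  }
  if (is.numeric(cc_label)) cc_label <- cc_label_from_index(cc_label)
  ci <- cc_index(cc_label) + 1L
  catalog$infer_table[cbind(as.integer(base_index) + 1L, ci)]
}

#' Read a DRG catalog from a delimited file
#'
#' @param path CSV or TSV file with columns `code`, `title` and optionally
#'   `version`; the delimiter is inferred from the extension (`.tsv` ->
#'   tab, otherwise comma).
#' @return A validated `drg_catalog`.
#' @export
read_drg_catalog <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", colClasses = "character")
  drg_catalog(tab)
}

#' Write the dissection of a catalog to a TSV file
#'
#' @param catalog a dissected catalog.
#' @param path output TSV path; columns `code`, `base_title`,
#'   `split_type`, `cc_label`.
#' @return The path, invisibly.
#' @export
write_dissection <- function(catalog, path) {
  if (!is_dissected(catalog)) stop("catalog must be dissected first")
  utils::write.table(
    catalog$dissection[, c("code", "base_title", "split_type", "cc_label")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
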