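# Synthetic catalogs, corpora and legacy titles with the statistical
# structure the method assumes: split families in realistic proportions,
# a long-tailed (Zipf) case distribution over codes, keyword-linked
# base-DRG signal, lexical severity cues for CC/MCC, and legacy-version
# title perturbations for harmonization testing.  Text is statistically,
# not medically, faithful.

# severity cue vocabulary, one disjoint word set per CC/MCC label, styled
# after the lexical cues coders look for
.cc_cues <- list(
  WITHOUT_CC_MCC = c("uncomplicated", "stable", "benign", "wellcontrolled"),
  WITH_CC        = c("anemia", "cellulitis", "dehydration", "exacerbation"),
  WITH_MCC       = c("septic", "shock", "intubated", "resuscitation"),
  WITHOUT_MCC    = c("convalescent", "uneventful", "ambulating", "tolerating"),
  NOT_APPLICABLE = c("observation", "overnight", "outpatient", "elective")
)

.syllables <- c("ba", "co", "da", "fe", "gi", "ho", "ju", "ka", "lu", "me",
                "ni", "po", "qua", "ru", "se", "ti", "vo", "wa", "xe", "zo")

#' Synthetic-generator configuration
#'
#' Defaults emulate the structure of the reference cohort: 340 base
#' families split 154/44/65/77 across the four family types (757 codes),
#' a Zipf case distribution over codes (imbalanced with a long tail),
#' three keyword tokens per base DRG, severity cues truthful 90% of the
#' time, and a 10% legacy-title perturbation rate.
#'
#' @param n_base_families number of base-DRG families.
#' @param split_mix proportions over the four split types, in
#'   [split_types()] order; must sum to 1.
#' @param n_records corpus size.
#' @param zipf_exponent Zipf exponent of the class-frequency law
#'   (larger = more head-heavy).
#' @param keyword_per_base base-specific keyword tokens per family.
#' @param severity_cue_strength probability that a record's severity cue
#'   words are truthful for its CC/MCC label (1 = noiseless).
#' @param noise_vocab_size size of the filler-word vocabulary.
#' @param legacy_perturb_rate fraction of unmappable legacy titles
#'   injected by [generate_legacy_titles()].
#' @param short_frac,dup_frac fractions of deliberately short /
#'   duplicated records injected to exercise [quality_filter()].
#' @param seed master seed; all generators derive their streams from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_base_families = 340L,
                             split_mix = c(154, 44, 65, 77) / 340,
                             n_records = 2000L,
                             zipf_exponent = 1.1,
                             keyword_per_base = 3L,
                             severity_cue_strength = 0.9,
                             noise_vocab_size = 500L,
                             legacy_perturb_rate = 0.1,
                             short_frac = 0,
                             dup_frac = 0,
                             seed = 1L) {
  stopifnot(n_base_families >= 1, n_records >= 1, keyword_per_base >= 1,
            noise_vocab_size >= 1, zipf_exponent > 0,
            severity_cue_strength >= 0, severity_cue_strength <= 1,
            legacy_perturb_rate >= 0, legacy_perturb_rate <= 1,
            short_frac >= 0, dup_frac >= 0, short_frac + dup_frac < 1)
  if (length(split_mix) != 4 || any(split_mix < 0) ||
      abs(sum(split_mix) - 1) > 1e-8) {
    stop("split_mix must be 4 non-negative proportions summing to 1")
  }
  structure(list(
    n_base_families = as.integer(n_base_families),
    split_mix = stats::setNames(split_mix, split_types()),
    n_records = as.integer(n_records),
    zipf_exponent = zipf_exponent,
    keyword_per_base = as.integer(keyword_per_base),
    severity_cue_strength = severity_cue_strength,
    noise_vocab_size = as.integer(noise_vocab_size),
    legacy_perturb_rate = legacy_perturb_rate,
    short_frac = short_frac, dup_frac = dup_frac,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# largest-remainder apportionment of families to split types
.apportion <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.pronounceable <- function(rng, n_syllables) {
  paste(rng$sample(.syllables, n_syllables, replace = TRUE), collapse = "")
}

# unique multi-word uppercase base titles that never collide with the
# severity-suffix grammar
.make_base_titles <- function(rng, n) {
  titles <- character(0)
  while (length(titles) < n) {
    cand <- toupper(paste(
      vapply(seq_len(rng$sample(2:3, 1)), function(i) {
        .pronounceable(rng, rng$sample(2:3, 1))
      }, character(1)),
      collapse = " "
    ))
    if (!cand %in% titles) titles <- c(titles, cand)
  }
  titles
}

#' Generate a synthetic MS-DRG catalog
#'
#' Families are apportioned to the four split types by largest remainder
#' on `split_mix`; each family gets a pronounceable multi-word base title
#' and the exact suffix set of its split type; code numbers are
#' sequential.  The default configuration reproduces the v34.0 census:
#' 340 families as 154/44/65/77, hence 757 codes.
#'
#' @param config a [generator_config()].
#' @return A validated `drg_catalog`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rng <- .seeded_rng(config$seed)
  n_fam <- .apportion(config$n_base_families, config$split_mix)
  fam_type <- rep(split_types(), times = n_fam)
  fam_type <- rng$sample(fam_type, length(fam_type))    # interleave types
  base_titles <- .make_base_titles(rng, config$n_base_families)

  rows <- list()
  code <- 1L
  for (i in seq_along(base_titles)) {
    suffixes <- .split_suffix_sets[[fam_type[i]]]
    for (sfx in suffixes) {
      title <- trimws(paste(base_titles[i], .suffix_rendering[[sfx]]))
      rows[[length(rows) + 1L]] <- data.frame(
        code = code, title = title, version = "34.0",
        stringsAsFactors = FALSE
      )
      code <- code + 1L
    }
  }
  drg_catalog(do.call(rbind, rows))
}

# deterministic base-specific keyword tokens derived from the title
.base_keywords <- function(base_title, k) {
  stem <- tolower(gsub("[^A-Za-z0-9]", "", base_title))
  paste0(stem, seq_len(k))
}

#' Generate a synthetic discharge-summary corpus
#'
#' Class frequencies follow a Zipf law over catalog codes.  Each note
#' carries a "Brief Hospital Course" header, the base DRG's keyword
#' tokens, severity cue words (truthful for the code's CC/MCC label with
#' probability `severity_cue_strength`, otherwise drawn for a different
#' label), filler noise words padding the narrative to at least 40
#' words, and a trailing section so extraction has a boundary to find.
#' Optional fractions of deliberately short and duplicated records are
#' injected with bookkeeping flags.
#'
#' @param catalog a validated `drg_catalog` (dissected internally).
#' @param config a [generator_config()].
#' @return data.frame of stay records: `stay_id`, `text`, `drg_title`,
#'   `code`, `drg_version`, plus bookkeeping columns `injected_short`
#'   and `injected_dup`.
#' @export
generate_corpus <- function(catalog, config) {
  stopifnot(inherits(catalog, "drg_catalog"),
            inherits(config, "generator_config"))
  if (!is_dissected(catalog)) catalog <- dissect(catalog)
  rng <- .seeded_rng(config$seed + 1L)
  dis <- catalog$dissection
  C <- nrow(dis)

  p <- seq_len(C)^(-config$zipf_exponent)
  cls <- rng$sample_int(C, config$n_records, replace = TRUE, prob = p / sum(p))
  noise_vocab <- paste0("filler",
                        sprintf("%04d", seq_len(config$noise_vocab_size)))

  body_for <- function(row) {
    kw <- rep(.base_keywords(dis$base_title[row], config$keyword_per_base),
              times = 3)
    truthful <- rng$runif(1) <= config$severity_cue_strength
    cue_label <- if (truthful) dis$cc_label[row] else
      rng$sample(setdiff(names(.cc_cues), dis$cc_label[row]), 1)
    cues <- rng$sample(.cc_cues[[cue_label]], 4, replace = TRUE)
    n_noise <- max(40L - length(kw) - length(cues),
                   rng$sample(20:45, 1))
    noise <- rng$sample(noise_vocab, n_noise, replace = TRUE)
    words <- rng$sample(c(kw, cues, noise), length(kw) + 4 + n_noise)
    paste(words, collapse = " ")
  }
  bodies <- vapply(cls, body_for, character(1))

  n <- config$n_records
  injected_short <- injected_dup <- rep(FALSE, n)
  n_short <- floor(config$short_frac * n)
  n_dup <- floor(config$dup_frac * n)
  if (n_short + n_dup > 0 && n >= 2) {
    targets <- rng$sample(2:n, min(n_short + n_dup, n - 1L))
    short_ix <- targets[seq_len(min(n_short, length(targets)))]
    dup_ix <- setdiff(targets, short_ix)
    for (i in short_ix) {
      bodies[i] <- paste(rng$sample(noise_vocab, 10, replace = TRUE),
                         collapse = " ")
      injected_short[i] <- TRUE
    }
    for (i in dup_ix) {
      src <- rng$sample(setdiff(seq_len(i - 1L), c(short_ix, dup_ix)), 1)
      bodies[i] <- bodies[src]
      injected_dup[i] <- TRUE
    }
  }

  data.frame(
    stay_id = sprintf("stay%06d", seq_len(n)),
    text = paste0("Admission Diagnosis:\nsynthetic\n\n",
                  "Brief Hospital Course:\n", bodies,
                  "\n\nMedications on Discharge:\nnone listed\n"),
    drg_title = catalog$codes$title[match(dis$code[cls],
                                          catalog$codes$code)],
    code = dis$code[cls],
    drg_version = "34.0",
    injected_short = injected_short,
    injected_dup = injected_dup,
    stringsAsFactors = FALSE
  )
}

#' Generate legacy-version titles with a truth map
#'
#' Produces one legacy rendering of every catalog title — abbreviation
#' inversions (WITHOUT -> W/O, WITH -> W) and lowercasing, which title
#' normalization undoes exactly — plus a `legacy_perturb_rate` fraction
#' of unmappable titles built on retired base-DRG families absent from
#' the catalog (the historical-code situation in which no appropriate
#' target exists).  The truth map records each title's intended
#' disposition.
#'
#' @param catalog a validated `drg_catalog`.
#' @param config a [generator_config()].
#' @return data.frame: `legacy_title`, `target_code` (NA where
#'   unmappable), `disposition` ("MAP" or "EXCLUDE").
#' @export
generate_legacy_titles <- function(catalog, config) {
  stopifnot(inherits(catalog, "drg_catalog"),
            inherits(config, "generator_config"))
  rng <- .seeded_rng(config$seed + 2L)

  abbreviate_title <- function(title) {
    toks <- strsplit(title, " ")[[1]]
    toks[toks == "WITHOUT"] <- "W/O"
    toks[toks == "WITH"] <- "W"
    paste(toks, collapse = " ")
  }
  legacy <- vapply(catalog$codes$title, function(tt) {
    if (rng$runif(1) < 0.7) tt <- abbreviate_title(tt)
    if (rng$runif(1) < 0.5) tt <- tolower(tt)
    tt
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(legacy_title = legacy,
                    target_code = catalog$codes$code,
                    disposition = "MAP", stringsAsFactors = FALSE)

  n_unmap <- round(config$legacy_perturb_rate * nrow(catalog$codes))
  if (n_unmap > 0) {
    existing <- unique(catalog$codes$base_title)
    retired <- character(0)
    while (length(retired) < n_unmap) {
      cand <- .make_base_titles(rng, 1L)
      if (!cand %in% existing && !cand %in% retired) {
        retired <- c(retired, cand)
      }
    }
    sfx <- rng$sample(c(" W MCC", " W CC", " W/O CC/MCC", ""),
                      n_unmap, replace = TRUE)
    out <- rbind(out, data.frame(
      legacy_title = paste0(retired, sfx),
      target_code = NA_integer_,
      disposition = "EXCLUDE", stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}
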