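# Evaluation harness: top-k accuracy, macro/micro F1, one-vs-rest AUC
# (midrank tie handling), bootstrap standard deviations, per-class
# frequency analysis, and the two-label report with final-DRG accuracy.

#' Ranked prediction matrix from logits
#'
#' @param logits numeric matrix, one row per record.
#' @return Integer matrix of 0-based label indices, each row the full
#'   descending-logit ranking with ties broken by ascending index.
#' @export
rank_predictions <- function(logits) {
  t(apply(logits, 1, function(x) order(-x, seq_along(x)) - 1L))
}

#' Top-k accuracy
#'
#' Fraction of records whose target label appears among the first `k`
#' ranked predictions.
#'
#' @param ranked integer matrix of 0-based ranked label indices (rows =
#'   records, columns = ranks), at least `k` columns.
#' @param targets 0-based integer target vector.
#' @param k cutoff rank (>= 1).
#' @return Proportion in \[0, 1\].
#' @export
topk_accuracy <- function(ranked, targets, k = 1L) {
  if (k < 1) stop("k must be at least 1")
  if (!is.matrix(ranked)) ranked <- matrix(ranked, ncol = length(ranked))
  if (ncol(ranked) < k) stop("ranked lists shorter than k")
  stopifnot(nrow(ranked) == length(targets))
  hits <- vapply(seq_along(targets),
                 function(i) targets[i] %in% ranked[i, seq_len(k)],
                 logical(1))
  mean(hits)
}

#' Macro- and micro-averaged F1
#'
#' Macro F1 is the unweighted mean of per-class F1 over the scored class
#' set; a class with no true and no predicted instances contributes 0.
#' Micro F1 pools counts globally: `TP / (TP + (FP + FN) / 2)`.  In
#' single-label multi-class scoring over all classes every error is one
#' FP plus one FN, so micro F1 equals top-1 accuracy.
#'
#' @param predictions 0-based top-1 predicted labels.
#' @param targets 0-based true labels.
#' @param averaging "macro" or "micro".
#' @param classes class set to score; defaults to the classes present in
#'   `targets` (set `classes = 0:(C-1)` to score all).
#' @return Score in \[0, 1\].
#' @export
f1_scores <- function(predictions, targets,
                      averaging = c("macro", "micro"),
                      classes = sort(unique(targets))) {
  averaging <- match.arg(averaging)
  stopifnot(length(predictions) == length(targets))
  if (length(classes) == 0) stop("empty class set")
  tp <- vapply(classes, function(cl) {
    sum(predictions == cl & targets == cl)
  }, numeric(1))
  fp <- vapply(classes, function(cl) {
    sum(predictions == cl & targets != cl)
  }, numeric(1))
  fn <- vapply(classes, function(cl) {
    sum(predictions != cl & targets == cl)
  }, numeric(1))
  if (averaging == "micro") {
    denom <- sum(tp) + (sum(fp) + sum(fn)) / 2
    return(if (denom == 0) 0 else sum(tp) / denom)
  }
  f1 <- ifelse(tp + (fp + fn) / 2 == 0, 0, tp / (tp + (fp + fn) / 2))
  mean(f1)
}

# one-vs-rest AUC by midrank: P(score_pos > score_neg) + 0.5 P(tie)
.binary_auc <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Macro- and micro-averaged one-vs-rest AUC
#'
#' Per-class receiver-operating-characteristic AUC of the class
#' probability against class membership, with midrank tie handling.
#' Macro averages over classes present in `targets` (a class lacking
#' positives or negatives is skipped with a warning); micro computes one
#' AUC on the stacked (record, class) binary problem.
#'
#' @param probs numeric probability matrix (rows = records, columns =
#'   labels in index order; rows should sum to 1).
#' @param targets 0-based true labels.
#' @param averaging "macro" or "micro".
#' @return AUC in \[0, 1\].
#' @export
auc_scores <- function(probs, targets, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  stopifnot(nrow(probs) == length(targets))
  if (max(abs(rowSums(probs) - 1)) > 1e-6) {
    stop("probability rows must sum to 1")
  }
  if (averaging == "micro") {
    member <- matrix(FALSE, nrow(probs), ncol(probs))
    member[cbind(seq_along(targets), targets + 1L)] <- TRUE
    return(.binary_auc(as.vector(probs), as.vector(member)))
  }
  classes <- sort(unique(targets))
  auc <- vapply(classes, function(cl) {
    .binary_auc(probs[, cl + 1L], targets == cl)
  }, numeric(1))
  if (anyNA(auc)) {
    warning(sum(is.na(auc)),
            " class(es) without both positives and negatives skipped")
  }
  mean(auc, na.rm = TRUE)
}

#' Bootstrap standard deviation of a metric
#'
#' Resamples the test set with replacement (resample size = test size)
#' `n_iter` times with a seeded generator and returns the sample
#' standard deviation (denominator n_iter - 1) of the metric across
#' resamples.
#'
#' @param metric function(index vector) -> scalar, evaluating the metric
#'   on the given record subset.
#' @param n_records number of test records.
#' @param n_iter bootstrap iterations (default 30, >= 2).
#' @param seed resampling seed.
#' @return List with `sd` and `values` (the per-iteration metric).
#' @export
bootstrap_sd <- function(metric, n_records, n_iter = 30L, seed = 1L) {
  stopifnot(n_iter >= 2, n_records >= 1)
  rng <- .seeded_rng(seed)
  values <- vapply(seq_len(n_iter), function(it) {
    metric(rng$sample_int(n_records, n_records, replace = TRUE))
  }, numeric(1))
  list(sd = stats::sd(values), values = values)
}

#' Per-class accuracy report
#'
#' One row per DRG label present in the test targets: training-case
#' count, test-case count and within-class top-`k` accuracy; plus a
#' banded summary (median and quartiles of training counts within bands
#' of accuracy) for frequency-vs-performance analysis.
#'
#' @param ranked ranked prediction matrix (0-based indices).
#' @param targets 0-based true labels.
#' @param train_counts named numeric vector: training cases per label
#'   index (names are 0-based indices as character).
#' @param k accuracy cutoff (default 5).
#' @param band_edges accuracy band boundaries (default `c(0.2, 0.8)`).
#' @return List with `per_class` (data.frame) and `bands` (data.frame).
#' @export
per_class_report <- function(ranked, targets, train_counts, k = 5L,
                             band_edges = c(0.2, 0.8)) {
  classes <- sort(unique(targets))
  missing <- setdiff(as.character(classes), names(train_counts))
  if (length(missing)) {
    stop("train_counts missing for class index(es): ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(classes, function(cl) {
    sel <- targets == cl
    hits <- vapply(which(sel), function(i) cl %in% ranked[i, seq_len(k)],
                   logical(1))
    data.frame(index = cl,
               n_train = as.numeric(train_counts[[as.character(cl)]]),
               n_test = sum(sel), accuracy = mean(hits))
  })
  per_class <- do.call(rbind, rows)

  edges <- sort(unique(c(0, band_edges, 1 + 1e-9)))
  band <- cut(per_class$accuracy, breaks = edges, right = FALSE,
              include.lowest = TRUE)
  bands <- do.call(rbind, lapply(levels(band), function(lv) {
    sel <- band == lv
    if (!any(sel)) return(NULL)
    q <- stats::quantile(per_class$n_train[sel], c(0.25, 0.5, 0.75))
    data.frame(band = lv, n_classes = sum(sel),
               q1_train = q[[1]], median_train = q[[2]], q3_train = q[[3]])
  }))
  list(per_class = per_class, bands = bands)
}

.metric_block <- function(logits, targets, ks = c(1L, 5L, 10L),
                          n_boot = 30L, seed = 1L) {
  ks <- ks[ks <= ncol(logits)]
  ranked <- rank_predictions(logits)
  probs <- t(apply(logits, 1, softmax))
  top1 <- ranked[, 1]

  vals <- list()
  for (k in ks) {
    vals[[paste0("acc", k)]] <- topk_accuracy(ranked, targets, k)
  }
  vals$macro_f1 <- f1_scores(top1, targets, "macro")
  vals$micro_f1 <- f1_scores(top1, targets, "micro")
  vals$macro_auc <- suppressWarnings(auc_scores(probs, targets, "macro"))
  vals$micro_auc <- auc_scores(probs, targets, "micro")

  sds <- list()
  boot_seed <- seed
  for (nm in names(vals)) {
    boot_seed <- boot_seed + 1L
    metric <- switch(
      sub("[0-9]+$", "", nm),
      acc = local({
        k <- as.integer(sub("acc", "", nm))
        function(ix) topk_accuracy(ranked[ix, , drop = FALSE],
                                   targets[ix], k)
      }),
      macro_f = function(ix) f1_scores(top1[ix], targets[ix], "macro"),
      micro_f = function(ix) f1_scores(top1[ix], targets[ix], "micro"),
      macro_auc = function(ix) suppressWarnings(
        auc_scores(probs[ix, , drop = FALSE], targets[ix], "macro")),
      micro_auc = function(ix) auc_scores(probs[ix, , drop = FALSE],
                                          targets[ix], "micro")
    )
    sds[[nm]] <- bootstrap_sd(metric, length(targets),
                              n_iter = n_boot, seed = boot_seed)$sd
  }
  data.frame(metric = names(vals), value = unlist(vals, use.names = FALSE),
             sd = unlist(sds, use.names = FALSE))
}

#' Evaluate single-label DRG predictions
#'
#' @param logits logit matrix over the DRG label space (rows = records).
#' @param targets 0-based DRG indices.
#' @param n_boot bootstrap iterations for standard deviations
#'   (default 30).
#' @param seed bootstrap seed.
#' @return Object of class `eval_report`: data.frame of metric, value,
#'   bootstrap sd.
#' @export
evaluate_single <- function(logits, targets, n_boot = 30L, seed = 1L) {
  out <- .metric_block(logits, targets, n_boot = n_boot, seed = seed)
  structure(list(metrics = out, scope = "all", n = length(targets)),
            class = "eval_report")
}

#' Evaluate two-label predictions with final-DRG mapping
#'
#' Scores the base-DRG block (over B labels) and the CC/MCC block (over
#' 5 labels) separately, then maps each record's dual argmax through the
#' catalog inference rule and reports final-DRG top-1 accuracy.  Final
#' accuracy can never exceed base accuracy: a wrong base DRG can never
#' map to the right code.
#'
#' @param joint_logits matrix of joint logits (B + 5 columns, base block
#'   first).
#' @param base_targets,cc_targets 0-based component targets.
#' @param target_codes true DRG code numbers.
#' @param catalog a dissected catalog.
#' @param n_boot bootstrap iterations (default 30).
#' @param seed bootstrap seed.
#' @return Object of class `eval_report` with `base`, `cc` metric blocks
#'   and `final_acc1` (+ bootstrap sd).
#' @export
evaluate_two_label <- function(joint_logits, base_targets, cc_targets,
                               target_codes, catalog, n_boot = 30L,
                               seed = 1L) {
  if (!is_dissected(catalog)) stop("catalog must be dissected first")
  B <- nrow(catalog$infer_table)
  stopifnot(ncol(joint_logits) == B + 5L)
  base_logits <- joint_logits[, seq_len(B), drop = FALSE]
  cc_logits <- joint_logits[, B + 1:5, drop = FALSE]

  base_block <- .metric_block(base_logits, base_targets,
                              n_boot = n_boot, seed = seed)
  cc_block <- .metric_block(cc_logits, cc_targets, ks = 1L,
                            n_boot = n_boot, seed = seed + 100L)

  pred_base <- max.col(base_logits, ties.method = "first") - 1L
  pred_cc <- max.col(cc_logits, ties.method = "first") - 1L
  final_code <- infer_drg(pred_base, pred_cc, catalog)
  hit <- final_code == target_codes
  final_sd <- bootstrap_sd(function(ix) mean(hit[ix]), length(hit),
                           n_iter = n_boot, seed = seed + 200L)$sd

  structure(list(base = base_block, cc = cc_block,
                 final_acc1 = mean(hit), final_acc1_sd = final_sd,
                 final_codes = final_code, n = length(hit)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(df) {
    df$value <- sprintf("%.3f", df$value)
    df$sd <- sprintf("(%.3f)", df$sd)
    df
  }
  if (!is.null(x$metrics)) {
    cat("Evaluation over", x$n, "records:\n")
    print(fmt(x$metrics), row.names = FALSE)
  } else {
    cat("Two-label evaluation over", x$n, "records\nBase DRG block:\n")
    print(fmt(x$base), row.names = FALSE)
    cat("CC/MCC block:\n")
    print(fmt(x$cc), row.names = FALSE)
    cat(sprintf("Final DRG ACC@1: %.3f (%.3f)\n",
                x$final_acc1, x$final_acc1_sd))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  to_list <- function(df) {
    stats::setNames(
      lapply(seq_len(nrow(df)),
             function(i) list(value = df$value[i], sd = df$sd[i])),
      df$metric
    )
  }
  out <- if (!is.null(report$metrics)) {
    to_list(report$metrics)
  } else {
    list(base = to_list(report$base), cc = to_list(report$cc),
         final = list(acc1 = list(value = report$final_acc1,
                                  sd = report$final_acc1_sd)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
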