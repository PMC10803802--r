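test_that("top-k accuracy counts hits like an exhaustive oracle", {
  ranked <- rbind(c(2L, 0L, 1L), c(0L, 1L, 2L), c(1L, 2L, 0L))
  targets <- c(1L, 0L, 0L)
  expect_equal(topk_accuracy(ranked, targets, 1), 1 / 3)
  expect_equal(topk_accuracy(ranked, targets, 3), 1)
  # target always at rank 3
  r3 <- matrix(rep(c(4L, 3L, 7L, 1L, 0L), 10), 10, 5, byrow = TRUE)
  expect_equal(topk_accuracy(r3, rep(7L, 10), 1), 0)
  expect_equal(topk_accuracy(r3, rep(7L, 10), 5), 1)
  # random rankings vs brute force; ACC@k non-decreasing in k
  set.seed(7)
  lg <- matrix(rnorm(200 * 10), 200)
  rk <- rank_predictions(lg)
  tg <- sample(0:9, 200, TRUE)
  accs <- vapply(1:10, function(k) topk_accuracy(rk, tg, k), numeric(1))
  brute <- mean(vapply(1:200, function(i) tg[i] == rk[i, 1], logical(1)))
  expect_equal(accs[1], brute)
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[10], 1)
  expect_lt(abs(accs[1] - 0.1), 0.06)       # chance level
  expect_error(topk_accuracy(rk, tg, 0), "at least 1")
})

test_that("F1 matches hand-worked confusion matrices; micro equals ACC@1", {
  # 3-class fixture: per-class F1 computed by hand
  truth <- c(0, 0, 0, 1, 1, 2)
  pred  <- c(0, 1, 0, 1, 2, 2)
  # class 0: tp 2 fp 0 fn 1 -> 4/5; class 1: tp 1 fp 1 fn 1 -> 1/2
  # class 2: tp 1 fp 1 fn 0 -> 2/3
  expect_equal(f1_scores(pred, truth, "macro"),
               mean(c(4 / 5, 1 / 2, 2 / 3)))
  expect_equal(oracle_f1(pred, truth, 0:2), c(4 / 5, 1 / 2, 2 / 3))
  expect_equal(f1_scores(pred, truth, "micro"), mean(pred == truth))
  expect_equal(f1_scores(truth, truth, "macro"), 1)
  expect_equal(f1_scores(truth, truth, "micro"), 1)
  # micro-F1 over all classes equals top-1 accuracy, 100 random sets
  set.seed(11)
  for (i in 1:100) {
    C <- sample(3:12, 1); n <- sample(10:60, 1)
    tg <- sample(0:(C - 1), n, TRUE)
    pr <- sample(0:(C - 1), n, TRUE)
    expect_equal(f1_scores(pr, tg, "micro", classes = 0:(C - 1)),
                 mean(pr == tg))
  }
})

test_that("one-vs-rest AUC equals the pair-counting oracle exactly", {
  set.seed(3)
  n <- 30; C <- 4
  lg <- matrix(rnorm(n * C), n)
  sig <- cbind(1:16, rep(1:4, 4))
  lg[sig] <- lg[sig] + 2                             # some signal + ties
  probs <- t(apply(lg, 1, softmax))
  tg <- sample(0:(C - 1), n, TRUE)
  for (cl in 0:(C - 1)) {
    expect_equal(
      drgkit:::.binary_auc(probs[, cl + 1], tg == cl),
      oracle_auc_pairs(probs[, cl + 1], tg == cl)
    )
  }
  macro <- auc_scores(probs, tg, "macro")
  oracle_macro <- mean(vapply(sort(unique(tg)), function(cl) {
    oracle_auc_pairs(probs[, cl + 1], tg == cl)
  }, numeric(1)))
  expect_equal(macro, oracle_macro)
  # cross-check against an established ROC implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    for (cl in 0:(C - 1)) {
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = as.integer(tg == cl), predictor = probs[, cl + 1],
        quiet = TRUE, direction = "<")))
      expect_equal(drgkit:::.binary_auc(probs[, cl + 1], tg == cl), ref,
                   tolerance = 1e-9)
    }
  }
  # perfect separation and chance level
  sep <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  expect_equal(auc_scores(rbind(sep, sep), c(0L, 1L, 0L, 1L), "macro"), 1)
  set.seed(5)
  p500 <- matrix(runif(500 * 3), 500); p500 <- p500 / rowSums(p500)
  expect_lt(abs(auc_scores(p500, sample(0:2, 500, TRUE), "macro") - 0.5),
            0.06)
  expect_error(auc_scores(p500 * 2, rep(0L, 500)), "sum to 1")
})

test_that("bootstrap SD is seeded, sane, and zero for constant metrics", {
  expect_equal(bootstrap_sd(function(ix) 0.7, 100, seed = 1)$sd, 0)
  # ACC@1 bootstrap at n=1000, p~0.5, against the binomial envelope
  set.seed(19)
  hit <- runif(1000) < 0.5
  bs <- bootstrap_sd(function(ix) mean(hit[ix]), 1000, n_iter = 30,
                     seed = 2)
  envelope <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(bs$sd, 3 * envelope)
  expect_gt(bs$sd, envelope / 3)
  # bit-for-bit determinism under the seed
  bs2 <- bootstrap_sd(function(ix) mean(hit[ix]), 1000, n_iter = 30,
                      seed = 2)
  expect_identical(bs$values, bs2$values)
  expect_error(bootstrap_sd(function(ix) 1, 10, n_iter = 1), "n_iter")
})

test_that("per-class report ties accuracy bands to training counts", {
  # single class, all correct
  rk <- matrix(c(0L, 1L), 1)
  out <- per_class_report(rk, 0L, c("0" = 5), k = 1)
  expect_equal(out$per_class$accuracy, 1)
  expect_equal(out$per_class$n_train, 5)
  # generator constructed so accuracy rises with class size
  n_per <- c(`0` = 40, `1` = 20, `2` = 8)
  acc_per <- c(0.9, 0.5, 0.1)
  set.seed(23)
  rows <- do.call(rbind, lapply(0:2, function(cl) {
    n <- n_per[[as.character(cl)]]
    hits <- runif(n) < acc_per[cl + 1]
    t(vapply(hits, function(h) {
      if (h) c(cl, (cl + 1) %% 3) else c((cl + 1) %% 3, (cl + 2) %% 3)
    }, numeric(2)))
  }))
  targets <- rep(0:2, times = n_per)
  out <- per_class_report(rows, targets, n_per, k = 1,
                          band_edges = c(0.2, 0.8))
  meds <- out$bands$median_train[order(out$bands$band)]
  expect_true(all(diff(out$bands$median_train) >= 0))
  expect_error(per_class_report(rows, targets, c("0" = 1), k = 1),
               "missing")
})

test_that("two-label evaluation scores blocks and the mapped final code", {
  d <- dissect(fixture_catalog())
  B <- nrow(d$infer_table)
  dis <- d$dissection
  n <- nrow(dis)
  # oracle predictor: logits peaked at the true component labels
  lg <- matrix(-4, n, B + 5)
  for (i in seq_len(n)) {
    lg[i, dis$base_index[i] + 1] <- 4
    lg[i, B + cc_index(dis$cc_label[i]) + 1] <- 4
  }
  ev <- evaluate_two_label(lg, dis$base_index, cc_index(dis$cc_label),
                           dis$code, d, n_boot = 5, seed = 3)
  expect_equal(ev$base$value[ev$base$metric == "acc1"], 1)
  expect_equal(ev$cc$value[ev$cc$metric == "acc1"], 1)
  expect_equal(ev$final_acc1, 1)
  # corrupt the CC/MCC block only: final accuracy degrades but never
  # exceeds base accuracy, and mapped codes match a direct recomputation
  set.seed(29)
  lg[, B + 1:5] <- rnorm(n * 5)
  ev2 <- evaluate_two_label(lg, dis$base_index, cc_index(dis$cc_label),
                            dis$code, d, n_boot = 5, seed = 3)
  expect_lte(ev2$final_acc1, ev2$base$value[ev2$base$metric == "acc1"])
  direct <- vapply(seq_len(n), function(i) {
    pr <- predict_two(lg[i, ], d)
    pr$code == dis$code[i]
  }, logical(1))
  expect_equal(ev2$final_acc1, mean(direct))
  expect_equal(ev2$final_codes, vapply(seq_len(n), function(i) {
    predict_two(lg[i, ], d)$code
  }, integer(1)))
})

test_that("metric blocks are invariant to record order", {
  set.seed(31)
  n <- 40; C <- 6
  lg <- matrix(rnorm(n * C), n)
  tg <- sample(0:(C - 1), n, TRUE)
  perm <- sample(n)
  rk <- rank_predictions(lg)
  probs <- t(apply(lg, 1, softmax))
  expect_equal(topk_accuracy(rk, tg, 3),
               topk_accuracy(rk[perm, ], tg[perm], 3))
  expect_equal(f1_scores(rk[, 1], tg, "macro"),
               f1_scores(rk[perm, 1], tg[perm], "macro"))
  expect_equal(auc_scores(probs, tg, "micro"),
               auc_scores(probs[perm, ], tg[perm], "micro"))
})
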