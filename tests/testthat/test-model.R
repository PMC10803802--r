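test_that("softmax is stable, sums to one, and is shift-invariant", {
  set.seed(1)
  for (n in c(5, 738)) {
    x <- rnorm(n, sd = 5)
    p <- softmax(x)
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_equal(softmax(x + 100), p, tolerance = 1e-12)
  }
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))  # no overflow
})

test_that("last-token logits match a step-by-step forward oracle", {
  # linear backbone: last embedding is the whole-sequence count vector
  bb <- linear_backbone(50, 4, init = "random", seed = 3)
  ids <- c(7L, 3L, 7L, 12L)
  counts <- tabulate(ids, 50)
  expect_equal(logits_last_token(bb, ids),
               drop(counts %*% bb$head$W) + bb$head$b)
  # per-token embeddings are the running sums
  emb <- backbone_forward(bb, ids)
  expect_equal(emb[2, 3], 1)
  expect_equal(emb[nrow(emb), ], counts)
  # zero head gives zero logits
  bb0 <- linear_backbone(50, 4)
  expect_equal(logits_last_token(bb0, ids), rep(0, 4))

  # attention backbone: independent position-by-position recomputation
  ab <- attention_backbone(50, 3, d = 8, seed = 5)
  X <- ab$E[ids, ] + ab$P[seq_along(ids), ]
  H <- matrix(0, length(ids), 8)
  for (i in seq_along(ids)) {          # causal: position i sees 1..i
    q <- X[i, , drop = FALSE] %*% ab$att$Wq
    Km <- X[1:i, , drop = FALSE] %*% ab$att$Wk
    Vm <- X[1:i, , drop = FALSE] %*% ab$att$Wv
    w <- drop(q %*% t(Km)) / sqrt(8)
    a <- exp(w - max(w)); a <- a / sum(a)
    H[i, ] <- X[i, ] + drop(matrix(a, 1) %*% Vm %*% ab$att$Wo)
  }
  expect_equal(backbone_forward(ab, ids), H, tolerance = 1e-6)
  expect_equal(logits_last_token(ab, ids),
               drop(H[length(ids), ] %*% ab$head$W) + ab$head$b,
               tolerance = 1e-6)
  # single-token input collapses to head(embedding of that token)
  one <- logits_last_token(ab, 9L)
  h1 <- ab$E[9L, ] + ab$P[1L, ]
  h1 <- h1 + drop((h1 %*% ab$att$Wv) %*% ab$att$Wo)  # self-attention of 1
  expect_equal(one, drop(h1 %*% ab$head$W) + ab$head$b, tolerance = 1e-6)
  expect_error(logits_last_token(bb, integer(0)), "empty")
})

test_that("losses match direct-evaluation oracles", {
  # uniform logits give ln C
  expect_equal(single_label_loss(rep(0, 7), 3L), log(7))
  # frozen value for a dominant logit
  expect_equal(single_label_loss(c(10, 0, 0), 0L), log1p(2 * exp(-10)),
               tolerance = 1e-9)
  expect_equal(single_label_loss(c(10, 0, 0), 0L), 9.0795738e-05,
               tolerance = 1e-6)
  # shift invariance
  set.seed(2)
  for (i in 1:100) {
    C <- sample(3:40, 1)
    lg <- rnorm(C, sd = 4)
    tgt <- sample(C, 1) - 1L
    expect_equal(single_label_loss(lg, tgt), oracle_ce(lg, tgt),
                 tolerance = 1e-6)
    expect_equal(single_label_loss(lg + 7.3, tgt),
                 single_label_loss(lg, tgt), tolerance = 1e-9)
  }
  expect_error(single_label_loss(rep(0, 5), 5L), "out of range")

  # two-label loss decomposes into the component cross-entropies
  expect_equal(two_label_loss(rep(0, 15), 2L, 1L, lambda = 0.5),
               log(10) + 0.5 * log(5))
  for (i in 1:50) {
    B <- sample(4:20, 1)
    lg <- rnorm(B + 5, sd = 3)
    bt <- sample(B, 1) - 1L; ct <- sample(5, 1) - 1L
    lam <- runif(1)
    expect_equal(two_label_loss(lg, bt, ct, lambda = lam, n_base = B),
                 oracle_ce(lg[1:B], bt) + lam * oracle_ce(lg[B + 1:5], ct),
                 tolerance = 1e-6)
  }
  # lambda 0 degenerates to the base-only loss
  lg <- rnorm(12)
  expect_equal(two_label_loss(lg, 1L, 3L, lambda = 0, n_base = 7L),
               single_label_loss(lg[1:7], 1L))
  expect_error(two_label_loss(lg, 1L, 3L, lambda = -1, n_base = 7L),
               "non-negative")
})

test_that("ranked predictions agree with a full-sort oracle", {
  set.seed(4)
  lg <- rnorm(20)
  top <- predict_single(lg, k = 10)
  expect_equal(top$index, order(-lg)[1:10] - 1L)
  expect_equal(sum(softmax(lg)), 1, tolerance = 1e-12)
  expect_equal(top$prob, softmax(lg)[top$index + 1L])
  # all-equal logits rank by ascending index
  flat <- predict_single(rep(1, 6), k = 6)
  expect_equal(flat$index, 0:5)
  # dominant logit ranks first
  lg[13] <- 99
  expect_equal(predict_single(lg, k = 1)$index, 12L)
})

test_that("dual argmax with mapping recovers catalog codes", {
  d <- dissect(fixture_catalog())
  B <- nrow(d$infer_table)
  peak <- function(bi, ci) {
    lg <- rep(-5, B + 5); lg[bi + 1] <- 5; lg[B + ci + 1] <- 5
    lg
  }
  # consistent targets round-trip to each catalog code
  for (i in seq_len(nrow(d$dissection))) {
    pr <- predict_two(peak(d$dissection$base_index[i],
                           cc_index(d$dissection$cc_label[i])), d)
    expect_equal(pr$code, d$dissection$code[i])
  }
  # mismatched severity falls back by split type
  two_way <- unname(d$label_space$base[["DEGENERATIVE NERVOUS SYSTEM DISORDERS"]])
  pr <- predict_two(peak(two_way, cc_index("WITH_CC")), d)
  expect_equal(pr$code, 57L)
  no_split <- unname(d$label_space$base[["TRANSIENT ISCHEMIA"]])
  pr <- predict_two(peak(no_split, cc_index("WITH_MCC")), d)
  expect_equal(pr$code, 69L)
})

test_that("adapters are exact identity at init and match the explicit oracle", {
  ab <- attention_backbone(60, 4, d = 12, seed = 9)
  spec <- adapter_spec(r = 2, alpha = 16)
  ad <- apply_adapters(ab, spec, seed = 11)
  ids <- c(5L, 44L, 17L, 2L, 30L)
  # B = 0 at init: bit-for-bit equality with the base model
  expect_identical(backbone_forward(ad, ids), backbone_forward(ab, ids))
  expect_identical(logits_last_token(ad, ids), logits_last_token(ab, ids))
  expect_equal(ad$trainable, "lora")

  # random factors: forward pass equals explicit W0 + (alpha/r) B A
  set.seed(13)
  explicit <- ab
  for (nm in names(ab$att)) {
    ad$lora[[nm]]$B <- matrix(rnorm(12 * 2, sd = 0.3), 12, 2)
    explicit$att[[nm]] <- ab$att[[nm]] +
      (spec$alpha / spec$r) * ad$lora[[nm]]$B %*% ad$lora[[nm]]$A
  }
  expect_equal(backbone_forward(ad, ids), backbone_forward(explicit, ids),
               tolerance = 1e-6)
  # full-rank limit is representable; oversized rank is rejected
  expect_s3_class(apply_adapters(ab, adapter_spec(r = 12, alpha = 12)),
                  "attention_backbone")
  expect_error(apply_adapters(ab, adapter_spec(r = 13)), "rank")
})

test_that("training reduces loss, respects zero learning rate, and is seeded", {
  cfg <- generator_config(n_base_families = 5, n_records = 150, seed = 31,
                          severity_cue_strength = 1)
  pipe <- fixture_pipeline(cfg, vocab = 1024)
  C <- nrow(pipe$catalog$codes)
  tc <- train_config(learning_rate = 1e-2, seed = 6)
  fit <- train(linear_backbone(1024, C), pipe$train, tc, mode = "single")
  expect_length(fit$trace, 3)
  expect_true(all(diff(fit$trace) <= 0))       # separable toy corpus
  # training accuracy reaches the ceiling
  lg <- predict_logits(fit$backbone, pipe$train)
  expect_equal(topk_accuracy(rank_predictions(lg), pipe$train$drg_index, 1),
               1.0)
  # determinism under the seed
  fit2 <- train(linear_backbone(1024, C), pipe$train, tc, mode = "single")
  expect_identical(fit$backbone$head, fit2$backbone$head)
  # zero learning rate leaves parameters unchanged
  frozen <- train(linear_backbone(1024, C), pipe$train,
                  train_config(learning_rate = 0, seed = 6),
                  mode = "single")
  expect_identical(frozen$backbone$head, linear_backbone(1024, C)$head)
  expect_error(train(linear_backbone(1024, C),
                     structure(list(n = 0), class = "drg_dataset"), tc),
               "empty")
})
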