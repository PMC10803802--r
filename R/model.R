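# Backbone-agnostic classification: last-token logits, single-label and
# two-label cross-entropy losses, dual-argmax inference with the catalog
# mapping rule, a low-rank adapter contract, and an AdamW training loop.
#
# Two reference backbones make the pipeline runnable at desk scale:
#   * linear_backbone(): bag-of-tokens scorer whose per-token "embedding"
#     is the running sum of one-hot token vectors, so the last-token
#     embedding is the whole-sequence token count vector;
#   * attention_backbone(): a tiny causal self-attention encoder with true
#     last-token semantics and adapter-targetable attention weights.
# Production LLM backbones plug in through the same generics.

#' Numerically stable softmax
#'
#' @param x numeric vector of logits (finite).
#' @return Probability vector summing to 1.
#' @export
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Linear bag-of-tokens reference backbone
#'
#' Token vectors are one-hot over the vocabulary and the per-token
#' embedding sequence is their running sum, so the embedding width equals
#' the vocabulary size and the last-token embedding is the token count
#' vector of the whole sequence.  The classification head is the only
#' parameterized component; training it is multinomial logistic
#' regression on token counts.
#'
#' @param vocab_size vocabulary size (match the tokenizer's).
#' @param n_labels output label count.
#' @param init "zero" (default) or "random" head initialization.
#' @param seed seed for random initialization.
#' @return Object of class `c("linear_backbone", "drg_backbone")`.
#' @export
linear_backbone <- function(vocab_size, n_labels,
                            init = c("zero", "random"), seed = 1L) {
  init <- match.arg(init)
  V <- as.integer(vocab_size); L <- as.integer(n_labels)
  W <- matrix(0, V, L)
  if (init == "random") {
    rng <- .seeded_rng(seed)
    W[] <- rng$rnorm(V * L, sd = 0.02)
  }
  structure(list(vocab_size = V, n_labels = L, d = V,
                 head = list(W = W, b = numeric(L))),
            class = c("linear_backbone", "drg_backbone"))
}

#' Tiny causal self-attention reference backbone
#'
#' One block of single-head causal self-attention with learned token and
#' position embeddings and a residual connection; deterministic given its
#' seed.  Small by construction (width <= 64) — it exists to exercise true
#' last-token pooling and the low-rank adapter contract, not to be a
#' competitive classifier.
#'
#' @param vocab_size vocabulary size.
#' @param n_labels output label count.
#' @param d embedding width (default 32, capped at 64).
#' @param max_len maximum sequence length (default 512).
#' @param seed parameter initialization seed.
#' @return Object of class `c("attention_backbone", "drg_backbone")`.
#' @export
attention_backbone <- function(vocab_size, n_labels, d = 32L,
                               max_len = 512L, seed = 1L) {
  d <- as.integer(d)
  stopifnot(d > 0, d <= 64)
  rng <- .seeded_rng(seed)
  mat <- function(nr, nc, sd = 0.08) {
    matrix(rng$rnorm(nr * nc, sd = sd), nr, nc)
  }
  structure(list(
    vocab_size = as.integer(vocab_size), n_labels = as.integer(n_labels),
    d = d, max_len = as.integer(max_len),
    E = mat(vocab_size, d), P = mat(max_len, d),
    att = list(Wq = mat(d, d), Wk = mat(d, d),
               Wv = mat(d, d), Wo = mat(d, d)),
    lora = NULL,
    head = list(W = mat(d, n_labels, sd = 0.02), b = numeric(n_labels))
  ), class = c("attention_backbone", "drg_backbone"))
}

# effective attention weight: frozen base plus scaled low-rank delta
.att_weight <- function(backbone, name) {
  W0 <- backbone$att[[name]]
  lr <- backbone$lora
  if (is.null(lr)) return(W0)
  W0 + (lr$spec$alpha / lr$spec$r) * (lr[[name]]$B %*% lr[[name]]$A)
}

#' Per-token embedding sequence of a backbone
#'
#' @param backbone a `drg_backbone`.
#' @param tokens integer vector of token ids (1-based, non-empty).
#' @return Numeric matrix, one row per token position, `backbone$d`
#'   columns.
#' @export
backbone_forward <- function(backbone, tokens) UseMethod("backbone_forward")

#' @export
backbone_forward.linear_backbone <- function(backbone, tokens) {
  .check_tokens(backbone, tokens)
  n <- length(tokens)
  onehot <- matrix(0, n, backbone$vocab_size)
  onehot[cbind(seq_len(n), tokens)] <- 1
  out <- apply(onehot, 2, cumsum)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)   # n = 1 collapses
  out
}

#' @export
backbone_forward.attention_backbone <- function(backbone, tokens) {
  .check_tokens(backbone, tokens)
  n <- length(tokens)
  if (n > backbone$max_len) stop("sequence longer than max_len")
  X <- backbone$E[tokens, , drop = FALSE] +
    backbone$P[seq_len(n), , drop = FALSE]
  Q <- X %*% .att_weight(backbone, "Wq")
  K <- X %*% .att_weight(backbone, "Wk")
  V <- X %*% .att_weight(backbone, "Wv")
  S <- Q %*% t(K) / sqrt(backbone$d)
  S[upper.tri(S)] <- -Inf                       # causal mask
  A <- t(apply(S, 1, softmax))
  if (n == 1) A <- matrix(A, 1, 1)
  X + (A %*% V) %*% .att_weight(backbone, "Wo")
}

.check_tokens <- function(backbone, tokens) {
  if (length(tokens) == 0) stop("empty token sequence")
  if (any(tokens < 1L | tokens > backbone$vocab_size)) {
    stop("token id outside vocabulary")
  }
  invisible(TRUE)
}

#' Last-token embedding of a backbone
#'
#' The pooled representation used for classification: causal models carry
#' sequence-level information in the final position's embedding.
#'
#' @inheritParams backbone_forward
#' @return Numeric vector of length `backbone$d`.
#' @export
last_embedding <- function(backbone, tokens) UseMethod("last_embedding")

#' @export
last_embedding.linear_backbone <- function(backbone, tokens) {
  .check_tokens(backbone, tokens)
  # running-sum embedding: the last position holds whole-sequence counts
  tabulate(tokens, nbins = backbone$vocab_size)
}

#' @export
last_embedding.attention_backbone <- function(backbone, tokens) {
  emb <- backbone_forward(backbone, tokens)
  if (is.matrix(emb)) emb[nrow(emb), ] else emb
}

#' Classification logits from the last token embedding
#'
#' Applies the linear classification head to the final position's
#' embedding only.
#'
#' @inheritParams backbone_forward
#' @return Numeric logit vector of length `backbone$n_labels`.
#' @export
logits_last_token <- function(backbone, tokens) {
  h <- last_embedding(backbone, tokens)
  drop(h %*% backbone$head$W) + backbone$head$b
}

#' Single-label cross-entropy loss
#'
#' Categorical cross-entropy of a DRG logit vector against an integer
#' target: `-log softmax(logits)[target]`.
#'
#' @param logits numeric logit vector over the C DRG labels.
#' @param target 0-based target index in \[0, C).
#' @return Non-negative scalar loss.
#' @export
single_label_loss <- function(logits, target) {
  C <- length(logits)
  if (length(target) != 1 || target < 0 || target >= C) {
    stop("target index out of range 0..", C - 1)
  }
  z <- logits - max(logits)
  log(sum(exp(z))) - z[target + 1L]
}

#' Two-label combined loss
#'
#' Cross-entropy of the base-DRG block of a joint logit vector plus
#' `lambda` times the cross-entropy of the CC/MCC block.  The joint
#' vector has the B base-DRG logits first and the 5 CC/MCC logits last.
#'
#' @param logits numeric joint logit vector of length B + 5.
#' @param base_target 0-based base-DRG index in \[0, B).
#' @param cc_target 0-based CC/MCC index in \[0, 5).
#' @param lambda weight of the CC/MCC term (default 1/2).
#' @param n_base B; defaults to `length(logits) - 5`.
#' @return Non-negative scalar loss.
#' @export
two_label_loss <- function(logits, base_target, cc_target, lambda = 0.5,
                           n_base = length(logits) - 5L) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (n_base < 1 || length(logits) != n_base + 5L) {
    stop("joint logit vector must have length n_base + 5")
  }
  if (cc_target < 0 || cc_target >= 5) stop("cc_target out of range 0..4")
  single_label_loss(logits[seq_len(n_base)], base_target) +
    lambda * single_label_loss(logits[n_base + 1:5], cc_target)
}

#' Ranked DRG predictions from a logit vector
#'
#' @param logits numeric logit vector over the DRG label space.
#' @param k number of top predictions to return (default 10, at most the
#'   label count).
#' @param codes optional vector of DRG code numbers aligned with the
#'   logit indices (index 0 first).
#' @return data.frame with `rank`, `index` (0-based), `prob` (from a full
#'   softmax, so probabilities over all labels sum to 1) and `code` when
#'   supplied.  Ties are broken by ascending index.
#' @export
predict_single <- function(logits, k = 10L, codes = NULL) {
  stopifnot(k >= 1, k <= length(logits))
  p <- softmax(logits)
  ord <- order(-logits, seq_along(logits))[seq_len(k)]
  out <- data.frame(rank = seq_len(k), index = ord - 1L, prob = p[ord])
  if (!is.null(codes)) out$code <- codes[ord]
  out
}

#' Dual-argmax prediction with catalog mapping
#'
#' Takes independent argmaxes of the base-DRG and CC/MCC slices of a
#' joint logit vector (ties to the lowest index) and maps the pair to a
#' final DRG code with [infer_drg()].
#'
#' @param logits joint logit vector of length B + 5 with the base block
#'   first.
#' @param catalog a dissected catalog with B base labels.
#' @return List with `base_index`, `cc_index` (both 0-based), `cc_label`
#'   and `code` (the final DRG code number).
#' @export
predict_two <- function(logits, catalog) {
  if (!is_dissected(catalog)) stop("catalog must be dissected first")
  B <- nrow(catalog$infer_table)
  if (length(logits) != B + 5L) {
    stop("joint logit vector must have length ", B + 5L)
  }
  base_index <- which.max(logits[seq_len(B)]) - 1L   # first max = low index
  cc_index <- which.max(logits[B + 1:5]) - 1L
  list(base_index = base_index, cc_index = cc_index,
       cc_label = cc_label_from_index(cc_index),
       code = infer_drg(base_index, cc_index, catalog))
}

#' Low-rank adapter specification
#'
#' Configuration of the low-rank adaptation contract: each targeted
#' weight matrix `W0` (d x k) is augmented to `W0 + (alpha/r) B A` with
#' trainable factors `B` (d x r, zero-initialized) and `A` (r x k); the
#' base weights stay frozen.  Dropout is the rate applied to the adapter
#' path during adapter training.
#'
#' @param r adapter rank (default 8).
#' @param alpha scaling numerator (default 16); the multiplicative
#'   scaling is `alpha / r`.
#' @param dropout adapter-path dropout rate (default 0.05).
#' @return Object of class `adapter_spec`.
#' @export
adapter_spec <- function(r = 8L, alpha = 16, dropout = 0.05) {
  stopifnot(r >= 1, alpha > 0, dropout >= 0, dropout < 1)
  structure(list(r = as.integer(r), alpha = alpha, dropout = dropout),
            class = "adapter_spec")
}

#' Attach low-rank adapters to the attention weights
#'
#' Targets the four attention projections (Wq, Wk, Wv, Wo).  `A` factors
#' are Gaussian-initialized, `B` factors start at zero, so the adapted
#' model's forward pass equals the base model's exactly at
#' initialization.  Only the adapter factors are marked trainable.
#'
#' @param backbone an `attention_backbone`.
#' @param spec an [adapter_spec()]; `r` must not exceed the weight
#'   dimensions.
#' @param seed initialization seed for the `A` factors.
#' @return The adapted backbone.
#' @export
apply_adapters <- function(backbone, spec = adapter_spec(), seed = 1L) {
  if (!inherits(backbone, "attention_backbone")) {
    stop("adapters target the attention backbone's projection weights")
  }
  stopifnot(inherits(spec, "adapter_spec"))
  d <- backbone$d
  if (spec$r > d) stop("adapter rank r exceeds min(d, k) = ", d)
  rng <- .seeded_rng(seed)
  lora <- list(spec = spec)
  for (name in names(backbone$att)) {
    lora[[name]] <- list(
      B = matrix(0, d, spec$r),
      A = matrix(rng$rnorm(spec$r * d, sd = 1 / spec$r), spec$r, d)
    )
  }
  backbone$lora <- lora
  backbone$trainable <- "lora"
  backbone
}

#' Training configuration
#'
#' Defaults follow the reference fine-tuning protocol: AdamW with
#' learning rate 2e-5 and decoupled weight decay 0.01, 3 epochs, batch
#' size 4, CC/MCC loss weight lambda = 1/2, 512-token input cap.  The
#' learning rate suits LLM fine-tuning; training a reference backbone
#' from scratch needs a from-scratch rate (around 1e-2).
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay (applied to head weights,
#'   not biases).
#' @param epochs training epochs.
#' @param batch_size records per optimizer step.
#' @param lambda CC/MCC loss weight, non-negative.
#' @param max_tokens input truncation length.
#' @param seed shuffling seed.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-5, weight_decay = 0.01,
                         epochs = 3L, batch_size = 4L, lambda = 0.5,
                         max_tokens = 512L, seed = 1L) {
  stopifnot(lambda >= 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda = lambda, max_tokens = as.integer(max_tokens),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a model-ready dataset from prepared stay records
#'
#' Tokenizes each record's narrative, truncates to `max_tokens`, and
#' attaches integer targets from the catalog's label space.
#'
#' @param records data.frame with `bhc_text` and `code` columns (codes in
#'   the catalog).
#' @param catalog a dissected catalog.
#' @param tokenizer a [hash_tokenizer()].
#' @param max_tokens truncation length.
#' @return List of class `drg_dataset`: `tokens` (list of id vectors),
#'   `code`, `drg_index`, `base_index`, `cc_index`, `n`.
#' @export
make_dataset <- function(records, catalog, tokenizer = hash_tokenizer(),
                         max_tokens = 512L) {
  if (!is_dissected(catalog)) stop("catalog must be dissected first")
  pos <- match(records$code, catalog$dissection$code)
  if (anyNA(pos)) {
    stop("records carry codes absent from the catalog: ",
         paste(unique(records$code[is.na(pos)]), collapse = ", "))
  }
  structure(list(
    tokens = lapply(records$bhc_text, tokenize_truncate,
                    tokenizer = tokenizer, max_tokens = max_tokens),
    stay_id = records$stay_id,
    code = records$code,
    drg_index = catalog$dissection$drg_index[pos],
    base_index = catalog$dissection$base_index[pos],
    cc_index = cc_index(catalog$dissection$cc_label[pos]),
    n = nrow(records)
  ), class = "drg_dataset")
}

# one AdamW step on a parameter list; state carries first/second moments
.adamw_step <- function(params, grads, state, lr, wd, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^step)
    vhat <- state$v[[nm]] / (1 - beta2^step)
    decay <- if (nm == "W") wd * params[[nm]] else 0
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + decay)
  }
  list(params = params, state = state)
}

#' Train a backbone's classification head
#'
#' Mini-batch AdamW (decoupled weight decay) on the cross-entropy
#' objective: single-label mode trains against the DRG index over C
#' labels; two-label mode trains the joint B+5 head with the combined
#' loss (base cross-entropy plus `lambda` times the CC/MCC
#' cross-entropy).  The head is the trainable surface of the reference
#' backbones; for the linear backbone that is the entire model.
#' Deterministic given `config$seed`.
#'
#' @param backbone a `drg_backbone` whose `n_labels` matches the mode's
#'   label-space size (C for single, B + 5 for two-label).
#' @param dataset a `drg_dataset` from [make_dataset()].
#' @param config a [train_config()].
#' @param mode "single" or "two_label".
#' @param n_base B, required in two-label mode (defaults to
#'   `n_labels - 5`).
#' @return List with the fitted `backbone` and `trace` (per-epoch mean
#'   training loss).
#' @export
train <- function(backbone, dataset, config = train_config(),
                  mode = c("single", "two_label"),
                  n_base = backbone$n_labels - 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "drg_dataset"),
            inherits(config, "train_config"))
  if (dataset$n == 0) stop("empty training set")
  L <- backbone$n_labels
  if (mode == "two_label" && (n_base < 1 || L != n_base + 5L)) {
    stop("two-label mode needs n_labels = n_base + 5")
  }
  if (mode == "single" && any(dataset$drg_index >= L)) {
    stop("dataset DRG indices exceed the label space")
  }

  # cache last-token features once; the head is what trains
  feats <- lapply(dataset$tokens, last_embedding, backbone = backbone)

  params <- backbone$head
  zeros <- lapply(params, function(p) p * 0)
  state <- list(m = zeros, v = zeros)
  rng <- .seeded_rng(config$seed)
  trace <- numeric(config$epochs)
  step <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- rng$sample_int(dataset$n, dataset$n)
    losses <- numeric(dataset$n)
    for (start in seq(1, dataset$n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, dataset$n)]
      gW <- params$W * 0; gb <- params$b * 0
      for (i in batch) {
        f <- feats[[i]]
        logits <- drop(f %*% params$W) + params$b
        if (mode == "single") {
          tgt <- dataset$drg_index[i]
          losses[i] <- single_label_loss(logits, tgt)
          dl <- softmax(logits)
          dl[tgt + 1L] <- dl[tgt + 1L] - 1
        } else {
          bt <- dataset$base_index[i]; ct <- dataset$cc_index[i]
          losses[i] <- two_label_loss(logits, bt, ct,
                                      lambda = config$lambda,
                                      n_base = n_base)
          dl <- numeric(L)
          pb <- softmax(logits[seq_len(n_base)])
          pb[bt + 1L] <- pb[bt + 1L] - 1
          pc <- softmax(logits[n_base + 1:5])
          pc[ct + 1L] <- pc[ct + 1L] - 1
          dl[seq_len(n_base)] <- pb
          dl[n_base + 1:5] <- config$lambda * pc
        }
        gW <- gW + outer(f, dl)
        gb <- gb + dl
      }
      nb <- length(batch)
      step <- step + 1L
      upd <- .adamw_step(params, list(W = gW / nb, b = gb / nb), state,
                         lr = config$learning_rate,
                         wd = config$weight_decay, step = step)
      params <- upd$params; state <- upd$state
    }
    trace[epoch] <- mean(losses)
  }
  backbone$head <- params
  list(backbone = backbone, trace = trace)
}

#' Logit matrix over a dataset
#'
#' @param backbone a fitted `drg_backbone`.
#' @param dataset a `drg_dataset`.
#' @return Numeric matrix, one row per record, `backbone$n_labels`
#'   columns.
#' @export
predict_logits <- function(backbone, dataset) {
  stopifnot(inherits(dataset, "drg_dataset"))
  t(vapply(dataset$tokens, function(ids) logits_last_token(backbone, ids),
           numeric(backbone$n_labels)))
}
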