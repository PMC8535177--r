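#' Configuration for domain-adaptive continued pretraining
#'
#' Defaults follow the reference recipe used to adapt a large pretrained
#' encoder to psychotherapy transcripts: 10,000 steps at learning rate 2e-5
#' with minibatch 64, a 64-token budget per segment pair, a 0.5 probability
#' of building deliberately short training pairs (transcripts are full of
#' short utterances), and a 15% masking rate.
#'
#' @param steps Number of optimizer updates.
#' @param learning_rate Adam learning rate.
#' @param batch_size Instances per update.
#' @param max_len Combined token budget for the two segments (specials not
#'   counted).
#' @param short_seq_prob Probability that a pair is truncated to a shorter
#'   sampled target length.
#' @param mask_rate Per-token masking probability.
#' @param seed RNG seed (instance sampling and batch order).
#' @return An object of class `ctrs_adapt_config`.
#' @export
adaptation_config <- function(steps = 10000L, learning_rate = 2e-5,
                              batch_size = 64L, max_len = 64L,
                              short_seq_prob = 0.5, mask_rate = 0.15,
                              seed = 1L) {
  stopifnot(steps >= 0, learning_rate > 0, batch_size >= 1, max_len >= 4,
            short_seq_prob >= 0, short_seq_prob <= 1,
            mask_rate >= 0, mask_rate <= 1)
  structure(list(steps = as.integer(steps), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_len = as.integer(max_len),
                 short_seq_prob = short_seq_prob, mask_rate = mask_rate,
                 seed = as.integer(seed)),
            class = "ctrs_adapt_config")
}

#' Scaled-down adaptation profile
#'
#' The small-encoder recipe used throughout the test suite: 500 steps at a
#' learning rate suited to a freshly initialized 2-layer/32-dimensional
#' encoder, batch 32, 32-token pairs.
#'
#' @inheritParams adaptation_config
#' @return A `ctrs_adapt_config`.
#' @export
tiny_adaptation_config <- function(steps = 500L, learning_rate = 3e-3,
                                   batch_size = 32L, max_len = 32L,
                                   seed = 1L) {
  adaptation_config(steps = steps, learning_rate = learning_rate,
                    batch_size = batch_size, max_len = max_len, seed = seed)
}

SPECIALS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
PAD_ID <- 1L; UNK_ID <- 2L; CLS_ID <- 3L; SEP_ID <- 4L; MASK_ID <- 5L

#' Collect the whitespace-token vocabulary of a corpus
#'
#' @param sessions List of sessions.
#' @return Sorted character vector of unique tokens.
#' @export
corpus_vocabulary <- function(sessions) {
  sort(unique(unlist(lapply(sessions, function(s)
    lapply(s$utterances, function(u)
      tokenize_crop(u$text, .Machine$integer.max))))))
}

#' A small trainable transformer encoder
#'
#' A compact encoder for scaled-down domain adaptation: token + learned
#' position + segment embeddings with layer normalization, `n_layers`
#' post-norm blocks of residual multi-head scaled-dot-product self-attention
#' and residual ReLU feed-forward, a next-utterance (pair-order)
#' classification head on the pooled (`tanh`-projected) `[CLS]` state, and a
#' masked-token head tied to the input embedding matrix. The whole backward
#' pass is hand-derived and finite-difference-checked in the test suite.
#'
#' @param vocab_tokens Character vector of corpus tokens (specials are
#'   prepended automatically).
#' @param dim Model width.
#' @param n_layers,n_heads Blocks and attention heads (`dim %% n_heads == 0`).
#' @param ff_dim Feed-forward inner width.
#' @param max_pos Maximum sequence length (with specials).
#' @param init_sd Gaussian initialization scale for weights (normalization
#'   gains start at 1).
#' @param seed Initialization seed.
#' @return An object of class `tiny_encoder`.
#' @export
tiny_encoder <- function(vocab_tokens, dim = 32L, n_layers = 2L,
                         n_heads = 2L, ff_dim = 64L, max_pos = 80L,
                         init_sd = 0.02, seed = 1L) {
  stopifnot(dim %% n_heads == 0L, n_layers >= 1L)
  vocab <- c(SPECIALS, setdiff(vocab_tokens, SPECIALS))
  set.seed(seed)
  V <- length(vocab)
  ini <- function(nr, nc) matrix(rnorm(nr * nc, 0, init_sd), nr, nc)
  p <- list(E = ini(V, dim), P = ini(max_pos, dim), S = ini(2L, dim),
            ln0.g = rep(1, dim), ln0.b = numeric(dim))
  for (l in seq_len(n_layers)) {
    pre <- sprintf("L%d.", l)
    for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- ini(dim, dim)
    p[[paste0(pre, "F1")]] <- ini(dim, ff_dim)
    p[[paste0(pre, "f1")]] <- numeric(ff_dim)
    p[[paste0(pre, "F2")]] <- ini(ff_dim, dim)
    p[[paste0(pre, "f2")]] <- numeric(dim)
    p[[paste0(pre, "lg1")]] <- rep(1, dim)
    p[[paste0(pre, "lb1")]] <- numeric(dim)
    p[[paste0(pre, "lg2")]] <- rep(1, dim)
    p[[paste0(pre, "lb2")]] <- numeric(dim)
  }
  p$Wp <- ini(dim, dim); p$bp <- numeric(dim)   # tanh pooler over [CLS]
  p$Wn <- ini(dim, 2L); p$bn <- numeric(2L)
  p$bv <- numeric(V)
  structure(list(vocab = vocab, dim = as.integer(dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
                 max_pos = as.integer(max_pos), params = p),
            class = "tiny_encoder")
}

#' @export
print.tiny_encoder <- function(x, ...) {
  cat("<tiny_encoder> ", x$n_layers, " layers x dim ", x$dim, " (",
      x$n_heads, " heads), vocabulary ", length(x$vocab), "\n", sep = "")
  invisible(x)
}

encoder_ids <- function(enc, tokens) {
  id <- match(tokens, enc$vocab)
  id[is.na(id)] <- UNK_ID
  id
}

# row-wise layer normalization; the length-n scale vector recycles down
# columns, matching rows of the n x d matrix
layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  xc <- X - rowMeans(X)
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(Y = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# stacked item-major layout: row (b-1)*T + t
encoder_forward <- function(enc, ids, seg, want_cache = FALSE) {
  p <- enc$params
  B <- nrow(ids); T_ <- ncol(ids)
  if (T_ > enc$max_pos) stop("sequence length ", T_, " exceeds max_pos")
  idx <- as.vector(t(ids)); sgv <- as.vector(t(seg))
  pos <- rep(seq_len(T_), B)
  ln0 <- layernorm_fwd(p$E[idx, , drop = FALSE] + p$P[pos, , drop = FALSE] +
                         p$S[sgv, , drop = FALSE], p$ln0.g, p$ln0.b)
  X <- ln0$Y
  dh <- enc$dim / enc$n_heads
  keymask <- matrix(idx != PAD_ID, B, T_, byrow = TRUE)
  caches <- vector("list", enc$n_layers)
  for (l in seq_len(enc$n_layers)) {
    pre <- sprintf("L%d.", l)
    Q <- X %*% p[[paste0(pre, "Wq")]]
    K <- X %*% p[[paste0(pre, "Wk")]]
    V <- X %*% p[[paste0(pre, "Wv")]]
    O <- matrix(0, nrow(X), enc$dim)
    A_list <- if (want_cache) vector("list", B * enc$n_heads)
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T_ + seq_len(T_)
      km <- keymask[b, ]
      for (h in seq_len(enc$n_heads)) {
        ch <- (h - 1L) * dh + seq_len(dh)
        sc <- tcrossprod(Q[rb, ch, drop = FALSE],
                         K[rb, ch, drop = FALSE]) / sqrt(dh)
        sc[, !km] <- -Inf
        A <- exp(sc - apply(sc, 1L, max))
        A <- A / rowSums(A)
        O[rb, ch] <- A %*% V[rb, ch, drop = FALSE]
        if (want_cache) A_list[[(b - 1L) * enc$n_heads + h]] <- A
      }
    }
    AO <- O %*% p[[paste0(pre, "Wo")]]
    ln1 <- layernorm_fwd(X + AO, p[[paste0(pre, "lg1")]],
                         p[[paste0(pre, "lb1")]])
    X1 <- ln1$Y
    Hpre <- X1 %*% p[[paste0(pre, "F1")]]
    Hf <- pmax(Hpre + rep(p[[paste0(pre, "f1")]], each = nrow(X1)), 0)
    ln2 <- layernorm_fwd(X1 + Hf %*% p[[paste0(pre, "F2")]] +
                           rep(p[[paste0(pre, "f2")]], each = nrow(X1)),
                         p[[paste0(pre, "lg2")]], p[[paste0(pre, "lb2")]])
    if (want_cache)
      caches[[l]] <- list(Xin = X, Q = Q, K = K, V = V, O = O, A = A_list,
                          X1 = X1, Hf = Hf, ln1 = ln1, ln2 = ln2)
    X <- ln2$Y
  }
  list(H = X, caches = caches, idx = idx, pos = pos, sgv = sgv,
       B = B, T = T_, dh = dh, ln0 = ln0)
}

softmax_rows <- function(Z) {
  e <- exp(Z - apply(Z, 1L, max))
  e / rowSums(e)
}

# combined MLM + NSP loss (means over masked positions / pairs), with
# optional gradients for every encoder parameter
encoder_loss <- function(enc, batch, want_grad = FALSE) {
  p <- enc$params
  fw <- encoder_forward(enc, batch$ids, batch$seg, want_cache = want_grad)
  H <- fw$H; B <- fw$B; T_ <- fw$T
  cls_rows <- (seq_len(B) - 1L) * T_ + 1L

  C <- H[cls_rows, , drop = FALSE]
  P_ <- tanh(C %*% p$Wp + rep(p$bp, each = B))
  nsp_logits <- P_ %*% p$Wn + rep(p$bn, each = B)
  nsp_prob <- softmax_rows(nsp_logits)
  ynsp <- as.integer(batch$is_next) + 1L   # 1 = not-next, 2 = next
  nsp_loss <- -mean(log(pmax(nsp_prob[cbind(seq_len(B), ynsp)], 1e-12)))

  mp <- batch$masked_rows          # stacked row indices
  mt <- batch$masked_target_ids
  if (length(mp)) {
    Hm <- H[mp, , drop = FALSE]
    ml <- tcrossprod(Hm, p$E) + rep(p$bv, each = length(mp))
    mpr <- softmax_rows(ml)
    mlm_loss <- -mean(log(pmax(mpr[cbind(seq_along(mp), mt)], 1e-12)))
  } else mlm_loss <- 0

  loss <- nsp_loss + mlm_loss
  out <- list(loss = loss, nsp_loss = nsp_loss, mlm_loss = mlm_loss,
              nsp_prob = nsp_prob)
  if (!want_grad) return(out)

  grads <- list()
  dH <- matrix(0, nrow(H), ncol(H))
  dnsp <- nsp_prob
  dnsp[cbind(seq_len(B), ynsp)] <- dnsp[cbind(seq_len(B), ynsp)] - 1
  dnsp <- dnsp / B
  grads$Wn <- crossprod(P_, dnsp)
  grads$bn <- colSums(dnsp)
  dP <- tcrossprod(dnsp, p$Wn) * (1 - P_^2)
  grads$Wp <- crossprod(C, dP)
  grads$bp <- colSums(dP)
  dH[cls_rows, ] <- dH[cls_rows, ] + tcrossprod(dP, p$Wp)

  dE_tied <- matrix(0, nrow(p$E), ncol(p$E))
  grads$bv <- numeric(nrow(p$E))
  if (length(mp)) {
    dml <- mpr
    dml[cbind(seq_along(mp), mt)] <- dml[cbind(seq_along(mp), mt)] - 1
    dml <- dml / length(mp)
    dH[mp, ] <- dH[mp, ] + dml %*% p$E
    dE_tied <- crossprod(dml, H[mp, , drop = FALSE])
    grads$bv <- colSums(dml)
  }

  dhd <- fw$dh
  for (l in rev(seq_len(enc$n_layers))) {
    pre <- sprintf("L%d.", l)
    cc <- fw$caches[[l]]
    # feed-forward block (residual + post-norm)
    l2 <- layernorm_bwd(dH, cc$ln2, p[[paste0(pre, "lg2")]])
    grads[[paste0(pre, "lg2")]] <- l2$dg
    grads[[paste0(pre, "lb2")]] <- l2$db
    dX2 <- l2$dX
    dHf <- dX2 %*% t(p[[paste0(pre, "F2")]])
    grads[[paste0(pre, "F2")]] <- crossprod(cc$Hf, dX2)
    grads[[paste0(pre, "f2")]] <- colSums(dX2)
    dpre <- dHf * (cc$Hf > 0)
    grads[[paste0(pre, "F1")]] <- crossprod(cc$X1, dpre)
    grads[[paste0(pre, "f1")]] <- colSums(dpre)
    dX1 <- dX2 + dpre %*% t(p[[paste0(pre, "F1")]])
    # attention block (residual + post-norm)
    l1 <- layernorm_bwd(dX1, cc$ln1, p[[paste0(pre, "lg1")]])
    grads[[paste0(pre, "lg1")]] <- l1$dg
    grads[[paste0(pre, "lb1")]] <- l1$db
    dX1 <- l1$dX
    dAO <- dX1
    grads[[paste0(pre, "Wo")]] <- crossprod(cc$O, dAO)
    dO <- dAO %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, nrow(dH), enc$dim)
    dK <- matrix(0, nrow(dH), enc$dim)
    dV <- matrix(0, nrow(dH), enc$dim)
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T_ + seq_len(T_)
      for (h in seq_len(enc$n_heads)) {
        ch <- (h - 1L) * dhd + seq_len(dhd)
        A <- cc$A[[(b - 1L) * enc$n_heads + h]]
        dOb <- dO[rb, ch, drop = FALSE]
        dA <- tcrossprod(dOb, cc$V[rb, ch, drop = FALSE])
        dV[rb, ch] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(A * dA))
        dQ[rb, ch] <- dS %*% cc$K[rb, ch, drop = FALSE] / sqrt(dhd)
        dK[rb, ch] <- crossprod(dS, cc$Q[rb, ch, drop = FALSE]) / sqrt(dhd)
      }
    }
    grads[[paste0(pre, "Wq")]] <- crossprod(cc$Xin, dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(cc$Xin, dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(cc$Xin, dV)
    dH <- dX1 + dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) + dV %*% t(p[[paste0(pre, "Wv")]])
  }
  l0 <- layernorm_bwd(dH, fw$ln0, p$ln0.g)
  grads$ln0.g <- l0$dg
  grads$ln0.b <- l0$db
  grads$E <- dE_tied + scatter_rows(l0$dX, fw$idx, nrow(p$E))
  grads$P <- scatter_rows(l0$dX, fw$pos, nrow(p$P))
  grads$S <- scatter_rows(l0$dX, fw$sgv, 2L)
  out$grads <- grads
  out
}

scatter_rows <- function(dX, group, n_rows) {
  out <- matrix(0, n_rows, ncol(dX))
  agg <- rowsum(dX, group)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# ---- pretraining instances -------------------------------------------------

#' Build masked pair-prediction instances from a corpus
#'
#' Positive pairs are consecutive utterances within a session (after optional
#' role filtering, under which the surviving turns count as consecutive);
#' negatives replace the second segment with a uniformly drawn utterance from
#' the corpus, re-drawn whenever the sample happens to be the true successor,
#' at a 50% negative rate. With probability `short_seq_prob` the pair is
#' truncated to a target length sampled below `max_len`. Masking selects each
#' token with probability `mask_rate`; of the selected tokens 80% become
#' `[MASK]`, 10% a random vocabulary token and 10% stay unchanged (the
#' standard recipe).
#'
#' @param sessions List of sessions.
#' @param config A [adaptation_config()].
#' @param role_filter Optional `"therapist"`/`"patient"` restriction.
#' @return List of instances, each with `tokens_a`, `tokens_b` (post-masking),
#'   `is_next`, `masked_positions` (1-based indices into the combined
#'   `[CLS] a [SEP] b [SEP]` sequence) and `masked_targets` (original
#'   tokens). Sessions with fewer than two utterances after filtering
#'   contribute nothing.
#' @export
build_instances <- function(sessions, config = adaptation_config(),
                            role_filter = NULL) {
  set.seed(config$seed)
  texts <- lapply(sessions, function(s) {
    if (!is.null(role_filter)) s <- filter_role(s, role_filter)
    tok <- lapply(s$utterances, function(u) tokenize_crop(u$text, config$max_len))
    tok[lengths(tok) > 0L]
  })
  texts <- texts[lengths(texts) >= 2L]
  if (!length(texts)) stop("no session yields a pair after filtering")
  vocab <- unique(unlist(texts))
  flat <- do.call(rbind, lapply(seq_along(texts), function(s)
    data.frame(s = s, i = seq_along(texts[[s]]))))

  instances <- list()
  for (s in seq_along(texts)) {
    utts <- texts[[s]]
    for (i in seq_len(length(utts) - 1L)) {
      a <- utts[[i]]
      is_next <- runif(1) < 0.5
      if (is_next) {
        b <- utts[[i + 1L]]
      } else {
        repeat {
          j <- sample.int(nrow(flat), 1L)
          if (!(flat$s[[j]] == s && flat$i[[j]] == i + 1L)) break
        }
        b <- texts[[flat$s[[j]]]][[flat$i[[j]]]]
      }
      target <- if (runif(1) < config$short_seq_prob)
        sample(seq.int(4L, max(4L, config$max_len - 1L)), 1L) else
        config$max_len
      while (length(a) + length(b) > target) {
        if (length(a) >= length(b)) a <- a[-length(a)] else b <- b[-length(b)]
      }
      if (!length(a) || !length(b)) next
      inst <- mask_pair(a, b, config$mask_rate, vocab)
      inst$is_next <- is_next
      instances[[length(instances) + 1L]] <- inst
    }
  }
  instances
}

mask_pair <- function(a, b, mask_rate, vocab) {
  la <- length(a); lb <- length(b)
  # combined coordinates: [CLS] a [SEP] b [SEP]
  pos_all <- c(1L + seq_len(la), 2L + la + seq_len(lb))
  toks <- c(a, b)
  hit <- which(runif(la + lb) < mask_rate)
  targets <- toks[hit]
  for (j in hit) {
    r <- runif(1)
    toks[[j]] <- if (r < 0.8) "[MASK]" else if (r < 0.9)
      sample(vocab, 1L) else toks[[j]]
  }
  list(tokens_a = toks[seq_len(la)],
       tokens_b = toks[la + seq_len(lb)],
       masked_positions = pos_all[hit],
       masked_targets = targets)
}

instances_to_batch <- function(enc, instances) {
  B <- length(instances)
  lens <- vapply(instances, function(x)
    3L + length(x$tokens_a) + length(x$tokens_b), 0L)
  T_ <- max(lens)
  ids <- matrix(PAD_ID, B, T_)
  seg <- matrix(1L, B, T_)
  masked_rows <- integer(0); masked_tids <- integer(0)
  for (b in seq_len(B)) {
    x <- instances[[b]]
    la <- length(x$tokens_a); lb <- length(x$tokens_b)
    row <- c(CLS_ID, encoder_ids(enc, x$tokens_a), SEP_ID,
             encoder_ids(enc, x$tokens_b), SEP_ID)
    ids[b, seq_along(row)] <- row
    seg[b, seq.int(la + 3L, T_)] <- 2L
    if (length(x$masked_positions)) {
      masked_rows <- c(masked_rows, (b - 1L) * T_ + x$masked_positions)
      masked_tids <- c(masked_tids, encoder_ids(enc, x$masked_targets))
    }
  }
  list(ids = ids, seg = seg,
       is_next = vapply(instances, `[[`, TRUE, "is_next"),
       masked_rows = masked_rows, masked_target_ids = masked_tids)
}

#' Continue pretraining an encoder on masked pair instances
#'
#' Runs exactly `config$steps` Adam updates of the combined masked-token +
#' pair-order objective over shuffled minibatches (recycling the instance
#' list as needed) and returns the adapted encoder; the input encoder is
#' left unmodified. `steps = 0` returns the encoder unchanged. A fixed seed
#' makes the instance order, and hence the result, fully reproducible.
#'
#' @param encoder A [tiny_encoder()].
#' @param instances Instance list from [build_instances()].
#' @param config A [adaptation_config()].
#' @param quiet Suppress progress messages.
#' @return The adapted `tiny_encoder`, with a `history` attribute
#'   (data frame: step, loss).
#' @export
continue_pretraining <- function(encoder, instances,
                                 config = tiny_adaptation_config(),
                                 quiet = TRUE) {
  stopifnot(inherits(encoder, "tiny_encoder"))
  if (!length(instances)) stop("empty instance stream")
  if (config$steps == 0L) return(encoder)
  set.seed(config$seed)
  params <- encoder$params
  state <- adam_init(params)
  order_ <- sample(seq_along(instances))
  cursor <- 1L
  hist <- data.frame(step = integer(0), loss = numeric(0))
  for (step in seq_len(config$steps)) {
    take <- min(config$batch_size, length(instances))
    if (cursor + take - 1L > length(order_)) {
      order_ <- sample(seq_along(instances)); cursor <- 1L
    }
    batch_idx <- order_[seq.int(cursor, cursor + take - 1L)]
    cursor <- cursor + take
    enc_cur <- encoder; enc_cur$params <- params
    batch <- instances_to_batch(enc_cur, instances[batch_idx])
    res <- encoder_loss(enc_cur, batch, want_grad = TRUE)
    upd <- adam_step(params, res$grads, state, config$learning_rate, step)
    params <- upd$params; state <- upd$state
    hist <- rbind(hist, data.frame(step = step, loss = res$loss))
    if (!quiet && step %% 50L == 0L)
      message(sprintf("step %4d  loss %.4f", step, res$loss))
  }
  encoder$params <- params
  attr(encoder, "history") <- hist
  encoder
}

#' Mean combined objective loss of an encoder on an instance set
#'
#' @param encoder A `tiny_encoder`.
#' @param instances Instance list.
#' @param batch_size Evaluation batch size.
#' @return Scalar mean loss (instance-weighted).
#' @export
adaptation_loss <- function(encoder, instances, batch_size = 64L) {
  splits <- split(seq_along(instances),
                  ceiling(seq_along(instances) / batch_size))
  tot <- 0
  for (ix in splits) {
    batch <- instances_to_batch(encoder, instances[ix])
    tot <- tot + encoder_loss(encoder, batch)$loss * length(ix)
  }
  tot / length(instances)
}

#' Next-utterance prediction accuracy
#'
#' Fraction of labeled pairs whose predicted adjacency matches the label.
#' Besides a trained [tiny_encoder()], `encoder` may be a plain function
#' mapping an instance list to logical predictions — convenient for oracle
#' or constant reference predictors.
#'
#' @param encoder A `tiny_encoder` or a `function(instances) -> logical`.
#' @param eval_pairs Nonempty instance list with `is_next` labels.
#' @param batch_size Evaluation batch size.
#' @return Accuracy in `[0, 1]`.
#' @export
nsp_accuracy <- function(encoder, eval_pairs, batch_size = 64L) {
  if (!length(eval_pairs)) stop("empty evaluation pair list")
  truth <- vapply(eval_pairs, `[[`, TRUE, "is_next")
  if (is.function(encoder)) return(mean(encoder(eval_pairs) == truth))
  stopifnot(inherits(encoder, "tiny_encoder"))
  preds <- logical(length(eval_pairs))
  splits <- split(seq_along(eval_pairs),
                  ceiling(seq_along(eval_pairs) / batch_size))
  for (ix in splits) {
    batch <- instances_to_batch(encoder, eval_pairs[ix])
    pr <- encoder_loss(encoder, batch)$nsp_prob
    preds[ix] <- pr[, 2L] > pr[, 1L]
  }
  mean(preds == truth)
}

#' Session-level train/eval split for adaptation
#'
#' @param sessions List of sessions.
#' @param eval_frac Evaluation fraction (default 0.1, the 90/10 recipe).
#' @param seed Shuffle seed.
#' @return List with `train` and `eval` session lists; no session appears in
#'   both, so no evaluation utterance can occur in a training instance.
#' @export
adaptation_split <- function(sessions, eval_frac = 0.1, seed = 1L) {
  set.seed(seed)
  n <- length(sessions)
  ne <- max(1L, round(eval_frac * n))
  ev <- sample.int(n, ne)
  list(train = sessions[-ev], eval = sessions[ev])
}

#' Use a trained encoder as an utterance-embedding backend
#'
#' Embeds an utterance by running the encoder over `[CLS] tokens [SEP]` and
#' average-pooling the last layer over the real token positions (special
#' boundary tokens excluded; a flag includes them for comparison).
#'
#' @param encoder A `tiny_encoder`.
#' @param max_tokens Tokenization crop.
#' @param include_specials Pool over `[CLS]`/`[SEP]` states too.
#' @return A `ctrs_backend` usable with [embed_utterance()] /
#'   [embed_corpus()].
#' @export
transformer_backend <- function(encoder, max_tokens = 64L,
                                include_specials = FALSE) {
  stopifnot(inherits(encoder, "tiny_encoder"))
  structure(list(name = paste0("transformer-d", encoder$dim),
                 dimension = encoder$dim, max_tokens = as.integer(max_tokens),
                 encoder = encoder, include_specials = include_specials),
            class = c("transformer_backend", "ctrs_backend"))
}

#' @export
embed_tokens.transformer_backend <- function(backend, tokens) {
  enc <- backend$encoder
  n <- length(tokens)
  if (!n) return(matrix(0, 0L, enc$dim))
  ids <- matrix(c(CLS_ID, encoder_ids(enc, tokens), SEP_ID), 1L)
  H <- encoder_forward(enc, ids, matrix(1L, 1L, n + 2L))$H
  if (backend$include_specials) H else H[1L + seq_len(n), , drop = FALSE]
}
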