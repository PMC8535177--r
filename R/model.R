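#' Model configuration for the session-scoring networks
#'
#' Both architectures share a frozen utterance-embedding input, one
#' bidirectional GRU layer, additive self-attention, and small MLP output
#' heads. `arch = "single"` scores the session with one attention head, an
#' MLP and a sigmoid (binary competence probability, trained with
#' class-weighted binary cross-entropy). `arch = "multi"` runs 11 attention
#' heads over the shared GRU states, one per CTRS code, each feeding its own
#' linear-output MLP trained with per-code mean squared error; the total CTRS
#' is their sum and the competence label its binarization at 40.
#'
#' Defaults follow the reference recipe: 64 GRU units per direction, 10-unit
#' attention scorers, a 20-unit ReLU hidden layer, Adam at 0.001, at most 200
#' epochs with early-stopping patience 10, and a 256-utterance cap with batch
#' 128 for therapist-only input (512/64 when all utterances are used).
#'
#' @param arch `"multi"` or `"single"`.
#' @param recurrent_units GRU hidden units per direction.
#' @param attention_hidden Attention scorer hidden units.
#' @param mlp_hidden MLP hidden units (ReLU).
#' @param learning_rate Adam initial learning rate.
#' @param max_epochs,patience Early-stopping schedule (patience in epochs
#'   without validation-loss improvement).
#' @param seq_cap Maximum utterances per session fed to the GRU.
#' @param batch_size Minibatch size.
#' @param use_metadata Concatenate the one-hot metadata vector into every
#'   head's MLP input.
#' @param seed Integer seed controlling initialization and batch order.
#' @return An object of class `ctrs_model_config`.
#' @export
model_config <- function(arch = c("multi", "single"),
                         recurrent_units = 64L, attention_hidden = 10L,
                         mlp_hidden = 20L, learning_rate = 0.001,
                         max_epochs = 200L, patience = 10L,
                         seq_cap = 256L, batch_size = 128L,
                         use_metadata = TRUE, seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(recurrent_units >= 1, attention_hidden >= 1, mlp_hidden >= 1,
            learning_rate > 0, max_epochs >= 1, patience >= 1,
            seq_cap >= 1, batch_size >= 1)
  structure(list(arch = arch, recurrent_units = as.integer(recurrent_units),
                 attention_hidden = as.integer(attention_hidden),
                 mlp_hidden = as.integer(mlp_hidden),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seq_cap = as.integer(seq_cap),
                 batch_size = as.integer(batch_size),
                 use_metadata = isTRUE(use_metadata),
                 seed = as.integer(seed)),
            class = "ctrs_model_config")
}

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -l, l), nin, nout)
}

n_heads <- function(config) if (config$arch == "multi") 11L else 1L

head_ids <- function(config) if (config$arch == "multi") CTRS_CODES else "total"

init_params <- function(config, d, m) {
  u <- config$recurrent_units; a <- config$attention_hidden
  h <- config$mlp_hidden
  p <- list()
  for (dir in c("f", "b")) {
    p[[paste0(dir, ".W")]] <- glorot(d, 3L * u)
    p[[paste0(dir, ".b")]] <- numeric(3L * u)
    for (g in c("Uz", "Ur", "Uh")) p[[paste0(dir, ".", g)]] <- glorot(u, u)
  }
  min_ <- if (config$use_metadata) 2L * u + m else 2L * u
  for (i in seq_len(n_heads(config))) {
    pre <- sprintf("h%02d.", i)
    p[[paste0(pre, "aW")]] <- glorot(2L * u, a)
    p[[paste0(pre, "ab")]] <- numeric(a)
    p[[paste0(pre, "av")]] <- glorot(a, 1L)[, 1L]
    p[[paste0(pre, "W1")]] <- glorot(min_, h)
    p[[paste0(pre, "b1")]] <- numeric(h)
    p[[paste0(pre, "W2")]] <- glorot(h, 1L)
    p[[paste0(pre, "b2")]] <- numeric(1L)
  }
  p
}

# ---- batch packing ---------------------------------------------------------

# Stacked layout: row (t-1)*B + b of X holds utterance t of session b
# (zero-padded past each session's length). `perm` reverses every sequence
# within its own valid length, so the backward GRU direction reuses the same
# kernel and padding stays trailing; applying `perm` twice is the identity.
pack_batch <- function(sessions, cap, use_metadata) {
  B <- length(sessions)
  lens <- vapply(sessions, function(s) min(nrow(s$vectors), as.integer(cap)), 0L)
  T_ <- max(lens)
  d <- ncol(sessions[[1L]]$vectors)
  X <- matrix(0, T_ * B, d)
  for (b in seq_len(B)) {
    L <- lens[[b]]
    X[(seq_len(L) - 1L) * B + b, ] <- sessions[[b]]$vectors[seq_len(L), ,
                                                            drop = FALSE]
  }
  tt <- rep(seq_len(T_), each = B); bb <- rep(seq_len(B), T_)
  lb <- lens[bb]
  src_t <- ifelse(tt <= lb, lb - tt + 1L, tt)
  meta <- if (use_metadata)
    do.call(rbind, lapply(sessions, `[[`, "metadata_vec")) else
    matrix(0, B, 0L)
  codes <- t(vapply(sessions, function(s)
    if (is.null(s$labels)) rep(NA_real_, 11L) else as.numeric(s$labels$codes),
    numeric(11L)))
  list(X = X, B = B, T = T_, lens = lens,
       valid = tt <= lb,                     # stacked-row validity
       perm = (src_t - 1L) * B + bb,
       group = bb,
       meta = meta, codes = codes,
       ids = vapply(sessions, `[[`, "", "session_id"))
}

# ---- forward / backward ----------------------------------------------------

bigru_forward <- function(params, batch, u) {
  X <- batch$X; B <- batch$B
  if (ncol(X) != nrow(params[["f.W"]]))
    stop("embedding dimension ", ncol(X), " does not match model input ",
         nrow(params[["f.W"]]))
  XPf <- X %*% params[["f.W"]]
  XPf <- XPf + rep(params[["f.b"]], each = nrow(XPf))
  f <- gru_forward_cpp(XPf[, 1:u, drop = FALSE],
                       XPf[, (u + 1):(2 * u), drop = FALSE],
                       XPf[, (2 * u + 1):(3 * u), drop = FALSE],
                       params[["f.Uz"]], params[["f.Ur"]], params[["f.Uh"]], B)
  Xr <- X[batch$perm, , drop = FALSE]
  XPb <- Xr %*% params[["b.W"]]
  XPb <- XPb + rep(params[["b.b"]], each = nrow(XPb))
  bk <- gru_forward_cpp(XPb[, 1:u, drop = FALSE],
                        XPb[, (u + 1):(2 * u), drop = FALSE],
                        XPb[, (2 * u + 1):(3 * u), drop = FALSE],
                        params[["b.Uz"]], params[["b.Ur"]], params[["b.Uh"]], B)
  list(H = cbind(f$H, bk$H[batch$perm, , drop = FALSE]),
       f = f, b = bk, Xr = Xr)
}

bigru_backward <- function(params, batch, fwd, dH, u) {
  grads <- list()
  dHf <- dH[, 1:u, drop = FALSE]
  dHb <- dH[, (u + 1):(2 * u), drop = FALSE][batch$perm, , drop = FALSE]
  for (dir in c("f", "b")) {
    cache <- if (dir == "f") fwd$f else fwd$b
    dd <- if (dir == "f") dHf else dHb
    g <- gru_backward_cpp(dd, cache$H, cache$Z, cache$R, cache$G,
                          params[[paste0(dir, ".Uz")]],
                          params[[paste0(dir, ".Ur")]],
                          params[[paste0(dir, ".Uh")]], batch$B)
    dXP <- cbind(g$dXz, g$dXr, g$dXh)
    Xin <- if (dir == "f") batch$X else fwd$Xr
    grads[[paste0(dir, ".W")]] <- crossprod(Xin, dXP)
    grads[[paste0(dir, ".b")]] <- colSums(dXP)
    grads[[paste0(dir, ".Uz")]] <- g$dUz
    grads[[paste0(dir, ".Ur")]] <- g$dUr
    grads[[paste0(dir, ".Uh")]] <- g$dUh
  }
  grads
}

masked_softmax <- function(smat, validmat) {
  smat[!validmat] <- -Inf
  mx <- apply(smat, 1L, max)
  e <- exp(smat - mx)
  e[!validmat] <- 0
  e / rowSums(e)
}

# Full forward (and optional backward) pass for one packed batch.
# y: single-task binary labels (0/1) if arch == "single".
model_pass <- function(params, batch, config, want_grad = FALSE,
                       class_w = NULL) {
  u <- config$recurrent_units
  B <- batch$B; T_ <- batch$T
  fwd <- bigru_forward(params, batch, u)
  H <- fwd$H
  validmat <- matrix(batch$valid, B, T_)   # B x T, column-major matches layout
  nh <- n_heads(config)
  preds <- matrix(0, B, nh)
  alphas <- vector("list", nh)
  caches <- if (want_grad) vector("list", nh)
  meta <- batch$meta
  for (i in seq_len(nh)) {
    pre <- sprintf("h%02d.", i)
    U1 <- tanh(H %*% params[[paste0(pre, "aW")]] +
                 rep(params[[paste0(pre, "ab")]], each = nrow(H)))
    s <- as.vector(U1 %*% params[[paste0(pre, "av")]])
    alpha <- masked_softmax(matrix(s, B, T_), validmat)
    w <- as.vector(alpha)
    ctx <- rowsum(H * w, group = batch$group, reorder = TRUE)
    zin <- if (config$use_metadata) cbind(ctx, meta) else ctx
    h1 <- zin %*% params[[paste0(pre, "W1")]]
    h1 <- pmax(h1 + rep(params[[paste0(pre, "b1")]], each = B), 0)
    out <- as.vector(h1 %*% params[[paste0(pre, "W2")]]) +
      params[[paste0(pre, "b2")]]
    preds[, i] <- out
    alphas[[i]] <- alpha
    if (want_grad) caches[[i]] <- list(U1 = U1, alpha = alpha, w = w,
                                       zin = zin, h1 = h1)
  }

  # loss and output-gradient by architecture (labels may be absent when the
  # pass is prediction-only)
  if (anyNA(batch$codes) && !want_grad) {
    loss <- NA_real_
    dout <- NULL
  } else if (config$arch == "multi") {
    Y <- batch$codes
    res <- preds - Y
    loss <- sum(colMeans(res^2))
    dout <- 2 * res / B
  } else {
    y <- as.numeric(binarize_total(rowSums(batch$codes)) == "high")
    p <- stats::plogis(preds[, 1L])
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    wgt <- class_w[y + 1L]
    loss <- mean(wgt * (-y * log(pc) - (1 - y) * log(1 - pc)))
    dout <- matrix(wgt * (p - y) / B, B, 1L)
  }

  result <- list(loss = loss, preds = preds, alphas = alphas,
                 lens = batch$lens, ids = batch$ids)
  if (!want_grad) return(result)

  grads <- list()
  dH <- matrix(0, nrow(H), ncol(H))
  for (i in seq_len(nh)) {
    pre <- sprintf("h%02d.", i)
    cc <- caches[[i]]
    dov <- dout[, i]
    grads[[paste0(pre, "W2")]] <- crossprod(cc$h1, dov)
    grads[[paste0(pre, "b2")]] <- sum(dov)
    dh1 <- tcrossprod(dov, params[[paste0(pre, "W2")]][, 1L]) * (cc$h1 > 0)
    grads[[paste0(pre, "W1")]] <- crossprod(cc$zin, dh1)
    grads[[paste0(pre, "b1")]] <- colSums(dh1)
    dzin <- tcrossprod(dh1, params[[paste0(pre, "W1")]])
    dctx <- dzin[, seq_len(2 * u), drop = FALSE]
    dctx_rep <- dctx[batch$group, , drop = FALSE]
    # context = sum_t alpha_t h_t: weight path and hidden path
    dalpha <- matrix(rowSums(H * dctx_rep), B, T_)
    ds <- cc$alpha * (dalpha - rowSums(cc$alpha * dalpha))
    dsv <- as.vector(ds)
    dU1 <- tcrossprod(dsv, params[[paste0(pre, "av")]]) * (1 - cc$U1^2)
    grads[[paste0(pre, "av")]] <- as.vector(crossprod(cc$U1, dsv))
    grads[[paste0(pre, "aW")]] <- crossprod(H, dU1)
    grads[[paste0(pre, "ab")]] <- colSums(dU1)
    dH <- dH + cc$w * dctx_rep + tcrossprod(dU1, params[[paste0(pre, "aW")]])
  }
  grads <- c(grads, bigru_backward(params, batch, fwd, dH, u))
  result$grads <- grads
  result
}

# ---- losses and weights (exposed operations) -------------------------------

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of `w[y] * (-y log p - (1-y) log(1-p))`. Probabilities
#' exactly at 0 or 1 are clamped by `1e-7` before taking logs.
#'
#' @param labels Binary vector (0/1 or logical), 1 = positive/"high".
#' @param probs Predicted probabilities, same length.
#' @param weights Length-2 per-class weights `c(w_negative, w_positive)`, or
#'   a single weight applied to all samples.
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(labels, probs, weights = c(1, 1)) {
  y <- as.numeric(labels)
  stopifnot(length(y) == length(probs), all(y %in% c(0, 1)))
  if (length(weights) == 1L) weights <- rep(weights, 2L)
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  mean(weights[y + 1L] * (-y * log(p) - (1 - y) * log(1 - p)))
}

#' Inverse-frequency class weights
#'
#' `w_c = n_total / (2 * n_c)`, so that balanced labels give unit weights and
#' `sum_c w_c n_c = n_total` always.
#'
#' @param labels Binary vector (0/1, logical, or factor with levels
#'   `low`/`high`).
#' @return Named length-2 vector `c(low = ..., high = ...)`.
#' @export
class_weights <- function(labels) {
  if (is.factor(labels)) labels <- as.numeric(labels == "high")
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  c(low = length(y) / (2 * n0), high = length(y) / (2 * n1))
}

#' Multi-task CTRS loss
#'
#' Sum over the 11 codes of the per-code mean squared error across the batch.
#' Predictions are *not* clipped inside the loss; the `[0, 6]` restriction is
#' applied only at inference.
#'
#' @param true_codes,pred_codes Numeric matrices `n x 11` (rows = sessions).
#' @return Scalar loss.
#' @export
multitask_loss <- function(true_codes, pred_codes) {
  true_codes <- as.matrix(true_codes); pred_codes <- as.matrix(pred_codes)
  if (!all(dim(true_codes) == dim(pred_codes)))
    stop("true and predicted code matrices must have identical dimensions")
  sum(colMeans((pred_codes - true_codes)^2))
}

# ---- exposed architectural primitives --------------------------------------

#' Run the bidirectional GRU encoder over one embedded session
#'
#' @param session A `ctrs_embedded` session.
#' @param model A fitted `ctrs_model` (or a raw parameter list with the
#'   encoder entries) whose input dimension matches the session vectors.
#' @param seq_cap Optional cap overriding the model configuration.
#' @return List with `hidden` (`L x 2*units` matrix: forward and backward
#'   outputs concatenated per position) and `mask` (length-`L` logical).
#' @export
encode_sequence <- function(session, model, seq_cap = NULL) {
  params <- if (inherits(model, "ctrs_model")) model$params else model
  u <- ncol(params[["f.Uz"]])
  cap <- seq_cap %||% if (inherits(model, "ctrs_model"))
    model$config$seq_cap else nrow(session$vectors)
  if (nrow(session$vectors) == 0L) stop("empty session")
  batch <- pack_batch(list(session), cap, use_metadata = FALSE)
  H <- bigru_forward(params, batch, u)$H
  list(hidden = H, mask = rep(TRUE, nrow(H)))
}

#' Additive self-attention over a hidden-state sequence
#'
#' Scores each position with `v' tanh(W h_t + b)`, softmaxes over valid
#' positions (masked positions get exactly zero weight) and returns the
#' attention-weighted context vector.
#'
#' @param hidden `L x d` matrix of hidden vectors, or the list returned by
#'   [encode_sequence()].
#' @param head_params List with `aW` (`d x a`), `ab` (length `a`), `av`
#'   (length `a`).
#' @param mask Optional logical vector of valid positions.
#' @param head_id Label recorded on the profile.
#' @return List with `context` (length-`d` vector) and `profile` (class
#'   `ctrs_attention`: `head_id`, `weights` summing to 1 over valid
#'   positions).
#' @export
additive_attention <- function(hidden, head_params, mask = NULL,
                               head_id = "total") {
  if (is.list(hidden) && !is.null(hidden$hidden)) {
    if (is.null(mask)) mask <- hidden$mask
    hidden <- hidden$hidden
  }
  L <- nrow(hidden)
  if (is.null(mask)) mask <- rep(TRUE, L)
  if (!any(mask)) stop("all positions are masked")
  s <- as.vector(tanh(hidden %*% head_params$aW +
                        rep(head_params$ab, each = L)) %*% head_params$av)
  s[!mask] <- -Inf
  e <- exp(s - max(s)); e[!mask] <- 0
  w <- e / sum(e)
  list(context = as.vector(crossprod(hidden, w)),
       profile = structure(list(head_id = head_id, weights = w),
                           class = "ctrs_attention"))
}

# ---- training --------------------------------------------------------------

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.numeric(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]][] <- as.numeric(params[[nm]]) - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) numeric(length(p))),
       v = lapply(params, function(p) numeric(length(p))))

check_labeled <- function(sessions, what) {
  if (any(vapply(sessions, function(s) is.null(s$labels), TRUE)))
    stop(what, " contains unlabeled sessions")
}

epoch_loss <- function(params, batches, config, class_w) {
  n <- sum(vapply(batches, `[[`, 0L, "B"))
  sum(vapply(batches, function(b)
    model_pass(params, b, config, FALSE, class_w)$loss * b$B, 0)) / n
}

#' Train a session-scoring network
#'
#' Adam optimization with early stopping on validation loss: training stops
#' after `patience` epochs without improvement (or at `max_epochs`) and the
#' parameters from the best-validation epoch are returned. The training and
#' validation sets must be therapist-disjoint so the early-stopping signal is
#' honest about generalization to new therapists.
#'
#' @param config A [model_config()].
#' @param train,val Lists of labeled `ctrs_embedded` sessions (see
#'   [embed_corpus()]); therapist-disjoint.
#' @param quiet Suppress per-epoch progress.
#' @return An object of class `ctrs_model`: `params`, `config`,
#'   `class_weights` (single-task), and `history` (per-epoch train/val loss).
#' @export
train_model <- function(config, train, val, quiet = TRUE) {
  stopifnot(inherits(config, "ctrs_model_config"), length(train) > 0)
  if (length(val) == 0L) stop("validation set must be nonempty")
  check_labeled(train, "training set"); check_labeled(val, "validation set")
  tt <- vapply(train, `[[`, "", "therapist_id")
  tv <- vapply(val, `[[`, "", "therapist_id")
  if (length(intersect(tt, tv)))
    stop("train and validation sets share therapists: ",
         paste(head(intersect(tt, tv), 3L), collapse = ", "))
  d <- ncol(train[[1L]]$vectors)
  m <- length(train[[1L]]$metadata_vec)
  if (config$use_metadata && m == 0L)
    stop("use_metadata = TRUE but sessions carry no metadata vector")

  set.seed(config$seed)
  params <- init_params(config, d, m)
  class_w <- if (config$arch == "single") {
    y <- vapply(train, function(s)
      binarize_total(s$labels$total) == "high", TRUE)
    unname(class_weights(as.numeric(y)))
  } else c(1, 1)

  # fixed length-sorted batches (minimal padding); order shuffled per epoch
  ord <- order(vapply(train, function(s) nrow(s$vectors), 0L))
  splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
  train_batches <- lapply(splits, function(ix)
    pack_batch(train[ix], config$seq_cap, config$use_metadata))
  vord <- order(vapply(val, function(s) nrow(s$vectors), 0L))
  vsplits <- split(vord, ceiling(seq_along(vord) / config$batch_size))
  val_batches <- lapply(vsplits, function(ix)
    pack_batch(val[ix], config$seq_cap, config$use_metadata))

  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L; step <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    tr_loss <- 0; n_tr <- 0L
    for (bi in sample(seq_along(train_batches))) {
      b <- train_batches[[bi]]
      pass <- model_pass(params, b, config, TRUE, class_w)
      step <- step + 1L
      upd <- adam_step(params, pass$grads, state, config$learning_rate, step)
      params <- upd$params; state <- upd$state
      tr_loss <- tr_loss + pass$loss * b$B; n_tr <- n_tr + b$B
    }
    v_loss <- epoch_loss(params, val_batches, config, class_w)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_loss / n_tr,
                                         val_loss = v_loss))
    if (!quiet)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      tr_loss / n_tr, v_loss))
    if (v_loss < best$loss - 1e-9) {
      best <- list(loss = v_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config,
                 class_weights = class_w, history = history,
                 best_epoch = best$epoch, input_dim = d, metadata_dim = m),
            class = "ctrs_model")
}

#' @export
print.ctrs_model <- function(x, ...) {
  cat("<ctrs_model> ", x$config$arch, "-task, ", x$config$recurrent_units,
      " GRU units x 2 directions, ", n_heads(x$config),
      " attention head(s)\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs; best validation loss ",
      format(min(x$history$val_loss), digits = 5), " at epoch ",
      x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Score embedded sessions with a trained model
#'
#' @param model A fitted `ctrs_model`.
#' @param sessions List of `ctrs_embedded` sessions.
#' @return List of `ctrs_prediction` objects: `session_id`; `prob_high`
#'   (single-task); `code_preds` (multi-task, clipped to `[0, 6]`),
#'   `total_pred` (= their sum), `label_pred` (binarized at 40, or 0.5 on the
#'   single-task probability); and `attention`, one [additive_attention()]
#'   profile per head over the session's real positions.
#' @export
predict_sessions <- function(model, sessions) {
  stopifnot(inherits(model, "ctrs_model"))
  config <- model$config
  out <- vector("list", length(sessions))
  names(out) <- vapply(sessions, `[[`, "", "session_id")
  ord <- order(vapply(sessions, function(s) nrow(s$vectors), 0L))
  splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
  for (ix in splits) {
    b <- pack_batch(sessions[ix], config$seq_cap, config$use_metadata)
    pass <- model_pass(model$params, b, config, FALSE, model$class_weights)
    hids <- head_ids(config)
    for (j in seq_along(ix)) {
      att <- lapply(seq_along(hids), function(i)
        structure(list(head_id = hids[[i]],
                       weights = pass$alphas[[i]][j, seq_len(b$lens[[j]])]),
                  class = "ctrs_attention"))
      if (config$arch == "multi") {
        cp <- pmin(pmax(pass$preds[j, ], 0), 6)
        names(cp) <- CTRS_CODES
        tot <- sum(cp)
        pr <- list(session_id = b$ids[[j]], prob_high = NULL,
                   code_preds = cp, total_pred = tot,
                   label_pred = binarize_total(tot), attention = att)
      } else {
        p <- stats::plogis(pass$preds[j, 1L])
        pr <- list(session_id = b$ids[[j]], prob_high = p, code_preds = NULL,
                   total_pred = NULL,
                   label_pred = factor(if (p >= 0.5) "high" else "low",
                                       levels = c("low", "high")),
                   attention = att)
      }
      out[[b$ids[[j]]]] <- structure(pr, class = "ctrs_prediction")
    }
  }
  out
}

#' @export
print.ctrs_prediction <- function(x, ...) {
  cat("<ctrs_prediction> ", x$session_id, ": ", sep = "")
  if (!is.null(x$code_preds))
    cat("total ", format(x$total_pred, digits = 4), " -> ",
        as.character(x$label_pred), "\n", sep = "")
  else
    cat("P(high) = ", format(x$prob_high, digits = 4), " -> ",
        as.character(x$label_pred), "\n", sep = "")
  invisible(x)
}
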