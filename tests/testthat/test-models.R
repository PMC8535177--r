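ns <- asNamespace("ctrscore")

test_that("sequence encoder obeys shape, reversal and pad-invariance contracts", {
  set.seed(1)
  d <- 5L; u <- 4L
  cfg <- model_config(recurrent_units = u, seed = 1)
  params <- ns$init_params(cfg, d, 0L)
  s1 <- random_embedded("a", 1L, d)
  out1 <- encode_sequence(s1, params, seq_cap = 16L)
  expect_identical(dim(out1$hidden), c(1L, 2L * u))

  # with shared direction weights, running the reversed sequence through the
  # forward half reproduces the backward half at mirrored positions
  for (nm in c("W", "b", "Uz", "Ur", "Uh"))
    params[[paste0("b.", nm)]] <- params[[paste0("f.", nm)]]
  s <- random_embedded("b", 7L, d)
  H <- encode_sequence(s, params, seq_cap = 16L)$hidden
  srev <- s
  srev$vectors <- s$vectors[7:1, , drop = FALSE]
  Hrev <- encode_sequence(srev, params, seq_cap = 16L)$hidden
  expect_close(H[, (u + 1):(2 * u)], Hrev[7:1, 1:u], tol = 1e-10)

  # padding another session into the batch leaves valid positions untouched
  s2 <- random_embedded("c", 3L, d)
  batch12 <- ns$pack_batch(list(s, s2), 16L, FALSE)
  H12 <- ns$bigru_forward(params, batch12, u)$H
  rows_s <- (seq_len(7L) - 1L) * 2L + 1L
  expect_close(H12[rows_s, ], H, tol = 1e-10)

  expect_error(encode_sequence(random_embedded("d", 2L, d + 1L), params,
                               seq_cap = 8L), "dimension")
})

test_that("additive attention matches a brute-force oracle and its edge cases", {
  set.seed(2)
  hp <- list(aW = matrix(rnorm(6 * 3), 6, 3), ab = rnorm(3), av = rnorm(3))
  # singleton: weight exactly 1, context = h1
  h1 <- matrix(rnorm(6), 1, 6)
  a1 <- additive_attention(h1, hp)
  expect_identical(a1$profile$weights, 1)
  expect_close(a1$context, as.vector(h1))
  # two identical rows: symmetric 0.5/0.5
  h2 <- rbind(h1, h1)
  expect_close(additive_attention(h2, hp)$profile$weights, c(0.5, 0.5))
  # 5-vector case against element-wise score/softmax/weighted-sum arithmetic
  H <- matrix(rnorm(5 * 6), 5, 6)
  got <- additive_attention(H, hp)
  sc <- numeric(5)
  for (t in 1:5) {
    pre <- tanh(as.vector(H[t, ] %*% hp$aW) + hp$ab)
    sc[[t]] <- sum(pre * hp$av)
  }
  w <- exp(sc) / sum(exp(sc))
  ctx <- rep(0, 6)
  for (t in 1:5) ctx <- ctx + w[[t]] * H[t, ]
  expect_close(got$profile$weights, w)
  expect_close(got$context, ctx)
  expect_equal(sum(got$profile$weights), 1, tolerance = 1e-12)
  # masked positions get zero weight; all-masked input is an error
  gm <- additive_attention(H, hp, mask = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(gm$profile$weights[c(2, 4)], c(0, 0))
  expect_equal(sum(gm$profile$weights), 1, tolerance = 1e-12)
  expect_error(additive_attention(H, hp, mask = rep(FALSE, 5)), "masked")
})

test_that("weighted binary cross-entropy matches hand arithmetic", {
  expect_lt(weighted_bce_loss(1, 1, c(1, 1)), 1e-5)    # clamped near-zero
  expect_equal(weighted_bce_loss(1, 0.5, c(1, 1)), log(2), tolerance = 1e-9)
  expect_equal(weighted_bce_loss(0, 0.5, c(2, 1)), 2 * log(2),
               tolerance = 1e-9)
  # scalar-loop oracle on random batches
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    y <- rbinom(n, 1, 0.4); p <- runif(n, 0.01, 0.99); w <- runif(2, 0.5, 2)
    acc <- 0
    for (i in seq_len(n))
      acc <- acc + w[y[i] + 1] * (-y[i] * log(p[i]) - (1 - y[i]) * log(1 - p[i]))
    expect_equal(weighted_bce_loss(y, p, w), acc / n, tolerance = 1e-9)
  }
})

test_that("class weights are inversely proportional to frequency", {
  w <- class_weights(c(0, 0, 0, 1))
  expect_equal(unname(w), c(4 / 6, 2), tolerance = 1e-12)
  expect_equal(unname(class_weights(c(0, 1, 0, 1))), c(1, 1))
  # conservation: sum_c w_c n_c = n
  set.seed(4)
  for (rep in 1:10) {
    y <- c(0, 1, rbinom(sample(2:30, 1), 1, runif(1, 0.2, 0.8)))
    w <- class_weights(y)
    expect_equal(w[["low"]] * sum(y == 0) + w[["high"]] * sum(y == 1),
                 length(y), tolerance = 1e-9)
  }
  expect_error(class_weights(c(1, 1, 1)), "both classes")
})

test_that("multi-task loss sums per-code mean squared errors", {
  Y <- matrix(runif(22, 0, 6), 2, 11)
  expect_identical(multitask_loss(Y, Y), 0)
  Y1 <- matrix(3, 1, 11); P1 <- Y1; P1[1, 4] <- 4
  expect_equal(multitask_loss(Y1, P1), 1)
  Y2 <- matrix(3, 2, 11); P2 <- Y2; P2[1, 2] <- 4; P2[2, 2] <- 5
  expect_equal(multitask_loss(Y2, P2), (1 + 4) / 2)
  expect_error(multitask_loss(Y2, P1), "dimensions")
  # scalar-loop oracle
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    A <- matrix(runif(n * 11, 0, 6), n, 11)
    B <- A + matrix(rnorm(n * 11), n, 11)
    acc <- 0
    for (cc in 1:11) {
      s <- 0
      for (i in 1:n) s <- s + (B[i, cc] - A[i, cc])^2
      acc <- acc + s / n
    }
    expect_equal(multitask_loss(A, B), acc, tolerance = 1e-9)
  }
})

test_that("analytic gradients match finite differences for both architectures", {
  set.seed(6)
  d <- 4L
  sessions <- lapply(1:3, function(i) random_embedded(i, sample(2:6, 1), d))
  for (arch in c("multi", "single")) {
    cfg <- model_config(arch = arch, recurrent_units = 3, attention_hidden = 3,
                        mlp_hidden = 4, seq_cap = 8, batch_size = 4, seed = 6)
    batch <- ns$pack_batch(sessions, cfg$seq_cap, TRUE)
    params <- ns$init_params(cfg, d, 3L)
    cw <- c(0.8, 1.7)
    pass <- ns$model_pass(params, batch, cfg, TRUE, cw)
    eps <- 1e-6
    worst <- 0
    for (nm in names(params)) {
      for (k in sample(seq_along(params[[nm]]), min(3, length(params[[nm]])))) {
        pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
        num <- (ns$model_pass(pp, batch, cfg, FALSE, cw)$loss -
                  ns$model_pass(pm, batch, cfg, FALSE, cw)$loss) / (2 * eps)
        ana <- as.numeric(pass$grads[[nm]])[k]
        worst <- max(worst, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
      }
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("multi-task predictions clip codes, sum exactly, and binarize at 40", {
  set.seed(7)
  cfg <- tiny_model_config(arch = "multi", seed = 7)
  train <- lapply(1:8, function(i) random_embedded(i, sample(3:10, 1), 6))
  val <- lapply(9:10, function(i) random_embedded(i, 5, 6))
  fit <- train_model(cfg, train, val)
  preds <- predict_sessions(fit, val)
  for (p in preds) {
    expect_true(all(p$code_preds >= 0 & p$code_preds <= 6))
    expect_identical(p$total_pred, sum(p$code_preds))
    expect_identical(as.character(p$label_pred),
                     as.character(binarize_total(p$total_pred)))
    expect_length(p$attention, 11L)
    for (a in p$attention)
      expect_equal(sum(a$weights), 1, tolerance = 1e-6)
  }
  # raw clipping contract
  expect_identical(pmin(pmax(c(7.2, -0.3, 3.0), 0), 6), c(6, 0, 3))
  expect_identical(as.character(binarize_total(sum(rep(4, 11)))), "high")
  expect_identical(as.character(binarize_total(38.5)), "low")
})

test_that("single-task probabilities live in (0,1) and are reproducible", {
  set.seed(8)
  cfg <- tiny_model_config(arch = "single", seed = 8)
  mixed <- stats::setNames(c(6L, 5L, 6L, 4L, 5L, 6L, 4L, 5L, 6L, 5L, 4L),
                           ctrs_code_names())
  train <- lapply(1:8, function(i) {
    s <- random_embedded(i, sample(3:10, 1), 6)
    if (i %% 2) s$labels <- ctrs_scores(mixed)  # both classes present
    s
  })
  val <- lapply(9:10, function(i) {
    s <- random_embedded(i, 5, 6)
    if (i == 9) s$labels <- ctrs_scores(mixed)
    s
  })
  fit <- train_model(cfg, train, val)
  p1 <- predict_sessions(fit, val)
  p2 <- predict_sessions(fit, val)
  for (j in seq_along(p1)) {
    expect_gt(p1[[j]]$prob_high, 0); expect_lt(p1[[j]]$prob_high, 1)
    expect_identical(p1[[j]]$prob_high, p2[[j]]$prob_high)
    expect_identical(as.character(p1[[j]]$label_pred),
                     if (p1[[j]]$prob_high >= 0.5) "high" else "low")
    expect_length(p1[[j]]$attention, 1L)
    expect_identical(p1[[j]]$attention[[1L]]$head_id, "total")
  }
  # same seed and data reproduce the training history exactly
  fit2 <- train_model(cfg, train, val)
  expect_identical(fit$history, fit2$history)
})

test_that("without metadata fusion, metadata content cannot affect predictions", {
  set.seed(9)
  cfg <- tiny_model_config(arch = "multi", use_metadata = FALSE, seed = 9)
  train <- lapply(1:8, function(i) random_embedded(i, sample(3:8, 1), 5))
  val <- lapply(9:10, function(i) random_embedded(i, 4, 5))
  fit <- train_model(cfg, train, val)
  scrambled <- lapply(val, function(s) {
    s$metadata_vec <- rnorm(length(s$metadata_vec), 100)
    s
  })
  pa <- predict_sessions(fit, val)
  pb <- predict_sessions(fit, scrambled)
  for (j in seq_along(pa))
    expect_identical(pa[[j]]$code_preds, pb[[j]]$code_preds)
})

test_that("early stopping returns the best-validation parameters", {
  set.seed(10)
  cfg <- model_config(arch = "multi", recurrent_units = 3, attention_hidden = 3,
                      mlp_hidden = 4, seq_cap = 8, batch_size = 4,
                      max_epochs = 30, patience = 3, seed = 10)
  train <- lapply(1:8, function(i) random_embedded(i, sample(3:8, 1), 5))
  val <- lapply(9:11, function(i) random_embedded(i, 4, 5))
  fit <- train_model(cfg, train, val)
  h <- fit$history
  expect_identical(fit$best_epoch, h$epoch[which.min(h$val_loss)])
  if (nrow(h) < cfg$max_epochs)  # stopped early: exactly patience epochs late
    expect_identical(nrow(h), fit$best_epoch + cfg$patience)
  # returned parameters really are the best-epoch ones
  vb <- ns$epoch_loss(fit$params,
                      list(ns$pack_batch(val, cfg$seq_cap, TRUE)), cfg,
                      fit$class_weights)
  expect_equal(vb, min(h$val_loss), tolerance = 1e-9)
})

test_that("training rejects unlabeled input, empty validation and leakage", {
  cfg <- tiny_model_config(arch = "multi", seed = 1)
  tr <- lapply(1:4, function(i) random_embedded(i, 4, 5))
  va <- lapply(5:6, function(i) random_embedded(i, 4, 5))
  bad <- tr; bad[[2L]]$labels <- NULL
  expect_error(train_model(cfg, bad, va), "unlabeled")
  expect_error(train_model(cfg, tr, list()), "nonempty")
  leak <- va; leak[[1L]]$therapist_id <- tr[[1L]]$therapist_id
  expect_error(train_model(cfg, tr, leak), "share therapists")
})
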