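test_that("instance construction balances negatives and masks at the target rate", {
  corpus <- generate_adjacency_corpus(n_sessions = 25, n_utterances = 25,
                                      seed = 3)
  cfg <- adaptation_config(batch_size = 8, max_len = 32, seed = 5)
  inst <- build_instances(corpus, cfg)
  expect_gt(length(inst), 400)
  # negative fraction within the binomial 99% CI of 0.5
  neg <- mean(!vapply(inst, `[[`, TRUE, "is_next"))
  n <- length(inst)
  expect_lt(abs(neg - 0.5), 3.3 * sqrt(0.25 / n))   # 99.9% binomial bound
  # masked fraction approximately the 15% rate
  n_tok <- sum(vapply(inst, function(x)
    length(x$tokens_a) + length(x$tokens_b), 0L))
  n_mask <- sum(vapply(inst, function(x) length(x$masked_positions), 0L))
  expect_lt(abs(n_mask / n_tok - cfg$mask_rate),
            4 * sqrt(0.15 * 0.85 / n_tok))
  # masked positions are distinct, in range, and point at real tokens
  for (x in inst[1:50]) {
    L <- length(x$tokens_a) + length(x$tokens_b) + 3L
    expect_identical(anyDuplicated(x$masked_positions), 0L)
    expect_true(all(x$masked_positions > 1 & x$masked_positions < L))
    expect_lte(length(x$tokens_a) + length(x$tokens_b), cfg$max_len)
    expect_identical(length(x$masked_positions), length(x$masked_targets))
  }
})

test_that("negative pairs are never the true successor", {
  # random filler plus shuffled order makes utterances unique; no masking
  # or truncation, so instance tokens equal corpus tokens verbatim
  corpus <- generate_adjacency_corpus(n_sessions = 10, n_utterances = 15,
                                      seed = 4)
  utts_by_session <- lapply(corpus, function(s)
    lapply(s$utterances, function(u) tokenize_crop(u$text, 10000L)))
  cfg <- adaptation_config(max_len = 64, short_seq_prob = 0, mask_rate = 0,
                           seed = 6)
  inst <- build_instances(corpus, cfg)
  neg <- Filter(function(x) !x$is_next, inst)
  expect_gt(length(neg), 50L)
  for (x in neg) {
    found_as_successor <- FALSE
    for (utts in utts_by_session) {
      hit <- which(vapply(utts, identical, TRUE, x$tokens_a))
      for (h in hit)
        if (h < length(utts) && identical(utts[[h + 1L]], x$tokens_b))
          found_as_successor <- TRUE
    }
    expect_false(found_as_successor)
  }
})

test_that("a session with fewer than two utterances contributes nothing", {
  s1 <- session_transcript("one", "t1",
                           list(utterance("therapist", "solo words here", 0, 1)))
  s2 <- session_transcript("two", "t2",
                           list(utterance("therapist", "first turn", 0, 1),
                                utterance("therapist", "second turn", 2, 3)))
  cfg <- adaptation_config(short_seq_prob = 0, mask_rate = 0, seed = 1)
  inst <- build_instances(list(s1, s2), cfg)
  expect_length(inst, 1L)
  expect_error(build_instances(list(s1), cfg), "no session yields")
  # the only pair in a 2-utterance corpus comes from that adjacency
  pos <- Filter(function(x) x$is_next, inst)
  if (length(pos))
    expect_identical(pos[[1L]]$tokens_a, c("first", "turn"))
})

test_that("zero-step adaptation is the identity and seeds reproduce runs", {
  corpus <- generate_adjacency_corpus(n_sessions = 8, n_utterances = 10,
                                      seed = 7)
  cfg <- tiny_adaptation_config(steps = 0, seed = 2)
  enc <- tiny_encoder(corpus_vocabulary(corpus), dim = 16, ff_dim = 24,
                      seed = 11)
  expect_identical(continue_pretraining(enc, build_instances(corpus, cfg),
                                        cfg), enc)
  # same seed twice: identical held-out loss; input encoder untouched
  cfg2 <- tiny_adaptation_config(steps = 12, batch_size = 8, seed = 3)
  inst <- build_instances(corpus, cfg2)
  snapshot <- enc$params
  ad1 <- continue_pretraining(enc, inst, cfg2)
  ad2 <- continue_pretraining(enc, inst, cfg2)
  expect_identical(enc$params, snapshot)
  ev <- inst[1:20]
  expect_identical(adaptation_loss(ad1, ev), adaptation_loss(ad2, ev))
  expect_false(identical(ad1$params$E, enc$params$E))
  expect_error(continue_pretraining(enc, list(), cfg2), "empty")
})

test_that("short adaptation strictly lowers the combined objective", {
  corpus <- generate_adjacency_corpus(n_sessions = 20, n_utterances = 15,
                                      seed = 8)
  cfg <- tiny_adaptation_config(steps = 200, batch_size = 16, max_len = 24,
                                seed = 4)
  inst <- build_instances(corpus, cfg)
  enc <- tiny_encoder(corpus_vocabulary(corpus), dim = 16, n_layers = 2,
                      ff_dim = 24, seed = 12)
  before <- adaptation_loss(enc, inst[1:100])
  adapted <- continue_pretraining(enc, inst, cfg)
  after <- adaptation_loss(adapted, inst[1:100])
  expect_lt(after, before)
  hist <- attr(adapted, "history")
  expect_identical(nrow(hist), 200L)
  expect_lt(mean(tail(hist$loss, 20)), mean(head(hist$loss, 20)))
})

test_that("pair-order accuracy scores oracles, constants and untrained encoders", {
  corpus <- generate_adjacency_corpus(n_sessions = 15, n_utterances = 12,
                                      seed = 9)
  cfg <- adaptation_config(max_len = 32, seed = 10)
  pairs <- head(build_instances(corpus, cfg), 150)
  truth <- vapply(pairs, `[[`, TRUE, "is_next")
  # oracle that reads the labels scores 1; constant predictor ~ label share
  expect_identical(nsp_accuracy(function(p)
    vapply(p, `[[`, TRUE, "is_next"), pairs), 1)
  expect_equal(nsp_accuracy(function(p) rep(TRUE, length(p)), pairs),
               mean(truth))
  # untrained encoder: within the binomial 99% CI of chance
  enc <- tiny_encoder(corpus_vocabulary(corpus), dim = 16, ff_dim = 24,
                      seed = 13)
  acc <- nsp_accuracy(enc, pairs)
  expect_lt(abs(acc - 0.5), 2.576 * sqrt(0.25 / length(pairs)))
  expect_error(nsp_accuracy(enc, list()), "empty")
})

test_that("encoder gradients match finite differences away from ReLU kinks", {
  voc <- sprintf("tok%02d", 1:12)
  # a larger-than-default init keeps pre-activations off the ReLU kinks,
  # where central differences are valid
  enc <- tiny_encoder(voc, dim = 8, n_layers = 2, n_heads = 2, ff_dim = 12,
                      max_pos = 20, init_sd = 0.3, seed = 3)
  inst <- list(
    list(tokens_a = c("tok01", "tok02"), tokens_b = c("tok03", "[MASK]"),
         is_next = TRUE, masked_positions = c(2L, 6L),
         masked_targets = c("tok01", "tok04")),
    list(tokens_a = "tok05", tokens_b = c("tok06", "tok07", "tok08"),
         is_next = FALSE, masked_positions = 4L, masked_targets = "tok06"))
  ns <- asNamespace("ctrscore")
  batch <- ns$instances_to_batch(enc, inst)
  res <- ns$encoder_loss(enc, batch, want_grad = TRUE)
  set.seed(14)
  worst <- 0
  for (nm in names(enc$params)) {
    for (k in sample(seq_along(enc$params[[nm]]),
                     min(4, length(enc$params[[nm]])))) {
      e2 <- enc; e2$params[[nm]][k] <- enc$params[[nm]][k] + 1e-5
      lp <- ns$encoder_loss(e2, batch)$loss
      e2$params[[nm]][k] <- enc$params[[nm]][k] - 1e-5
      lm <- ns$encoder_loss(e2, batch)$loss
      num <- (lp - lm) / 2e-5
      ana <- as.numeric(res$grads[[nm]])[k]
      worst <- max(worst, abs(num - ana) / max(1e-5, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the session-level split keeps evaluation sessions out of training", {
  corpus <- generate_adjacency_corpus(n_sessions = 20, n_utterances = 6,
                                      seed = 15)
  sp <- adaptation_split(corpus, eval_frac = 0.1, seed = 5)
  expect_length(sp$eval, 2L)
  expect_length(sp$train, 18L)
  ids <- function(ss) vapply(ss, `[[`, "", "session_id")
  expect_length(intersect(ids(sp$train), ids(sp$eval)), 0L)
})

test_that("a trained encoder can serve as an embedding backend", {
  corpus <- generate_adjacency_corpus(n_sessions = 5, n_utterances = 6,
                                      seed = 16)
  enc <- tiny_encoder(corpus_vocabulary(corpus), dim = 16, ff_dim = 24,
                      seed = 17)
  be <- transformer_backend(enc)
  v <- embed_utterance("tpq01xz w001 tpq02xz", be)
  expect_length(v, 16L)
  expect_true(all(is.finite(v)))
  expect_identical(v, embed_utterance("tpq01xz w001 tpq02xz", be))
  # single-token utterance embeds as that token's (contextual) state
  expect_length(embed_utterance("w001", be), 16L)
  expect_identical(embed_utterance("", be), rep(0, 16L))
})
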