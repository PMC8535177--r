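# ctrscore

Automated session-level quality scoring of Cognitive Behavioral Therapy
(CBT) transcripts on the Cognitive Therapy Rating Scale (CTRS).

## The problem

CBT quality is monitored by *behavioral coding*: a trained rater reads a
whole session transcript and scores eleven CTRS codes (agenda, feedback,
understanding, interpersonal effectiveness, collaboration, pacing, guided
discovery, key cognitions & behaviors, strategy for change, application of
techniques, homework), each on a 0–6 Likert scale. The total score
(0–66) is the working competence metric; a total ≥ 40 indicates competent
delivery. Manual coding does not scale to routine care, so `ctrscore`
implements an automatic scoring pipeline for coded, role-tagged session
transcripts — for computational-psychotherapy researchers and for anyone
building quality-assurance tooling around dialogue-level behavioral codes.

## What is inside

The core is a hierarchical attention model over the session's utterance
sequence. Each utterance is embedded as a fixed vector (mean-pooled token
representations from a pluggable backend); the sequence
`x_1, …, x_L` runs through a bidirectional GRU, giving contextual states
`h_t = [→h_t; ←h_t]`; an additive self-attention head scores each talk turn,

    score_t = v' tanh(W h_t + b),   α = softmax(score),   c = Σ_t α_t h_t,

and the context vector `c` (optionally concatenated with one-hot session
metadata: clinic, level of care, population, assessment time) feeds a small
MLP. Two architectures share this trunk:

* **single-task** — one head, sigmoid output `P(total CTRS ≥ 40)`, trained
  with class-weighted binary cross-entropy;
* **multi-task** — eleven attention heads over the shared GRU states, one
  linear-output MLP per code trained with `L = Σ_i MSE_i`; at inference the
  code predictions are clipped to `[0, 6]`, summed, and binarized at 40.

Around the model: JSONL transcript I/O with talk-turn merging (< 2 s
same-role gaps) and role filtering; a deterministic hash embedding backend
plus a small trainable transformer encoder with masked-token +
next-utterance continued pretraining; a tf-idf → F-test(k = 32) → linear
SVM reference system; therapist-grouped k-fold cross-validation, macro-F1,
and a paired bootstrap test; time-normalized attention saliency curves; and
a seeded synthetic-corpus generator that emulates coded therapy corpora so
the whole pipeline runs without clinical data. The GRU time loops are
compiled (RcppArmadillo); all network gradients are hand-derived and
finite-difference-checked in the test suite.

## Worked example

```r
library(ctrscore)

# a synthetic coded corpus at the default study scale: 60 therapists x 10
# sessions, ~430 talk turns each
corpus <- generate_corpus(simulation_config(seed = 7))
split <- make_splits(corpus$sessions, c(train = .9, test = .1), seed = 1)

fit <- ctrs_scorer(split$train, arch = "multi",
                   backend = hash_embed_backend(64, seed = 2),
                   recurrent_units = 32, batch_size = 32,
                   learning_rate = 0.002, max_epochs = 80,
                   patience = 25, seed = 3)
fit
#> <ctrs_scorer> multi-task CTRS scorer
#>   540 training sessions (therapist utterances, backend hash64-s2)
#>   GRU 32x2 | attention 11 head(s) x 10 | metadata fused
#>   stopped after 80 epochs (best epoch 73, val loss 11.297)

preds <- predict(fit, split$test)
head(preds[, c("session_id", "ag", "hw", "total_pred", "label_pred")], 3)
#>   session_id       ag       hw total_pred label_pred
#> 1      S0041 3.694986 2.106960   28.33169        low
#> 2      S0042 2.568033 3.146438   28.83432        low
#> 3      S0043 2.460419 2.550254   27.77468        low

truth <- binarize_total(sapply(split$test, function(s) s$labels$total))
macro_f1(truth, preds$label_pred)
#> [1] 0.7777778
```

Each row of `preds` is one held-out session (these three are from a
low-skill therapist): per-code predictions on the 0–6 scale, their sum
`total_pred`, and the binarized competence label — macro-F1 is computed
over the held-out therapists' sessions.
`plot(fit, "saliency")` shows where in the session each code's attention
concentrates (agenda-like codes front-load; homework-like codes attend to
both ends), and `plot(fit, "history")` the training curves. Lower-level
surfaces (`train_model`, `crossvalidate_model`, `run_experiment_grid`,
`fit_baseline`, `paired_bootstrap`, `continue_pretraining`, …) expose every
stage individually; the vignette documents the models and all design
choices.

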