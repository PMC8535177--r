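---
title: "Session-level CBT quality scoring: models, data model, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Session-level CBT quality scoring: models, data model, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrscore)
```

## The problem

Behavioral coding is the gold standard for monitoring the quality of
Cognitive Behavioral Therapy (CBT): a trained coder reads or listens to a
full session and scores it on the Cognitive Therapy Rating Scale (CTRS) —
eleven codes (agenda, feedback, understanding, interpersonal effectiveness,
collaboration, pacing, guided discovery, key cognitions and behaviors,
strategy for change, application of techniques, homework), each on a 0–6
Likert scale. The total (0–66) is the working competence metric; a total at
or above 40 is read as competent CBT delivery. Human coding does not scale,
which motivates automatic session-level scoring from transcripts.

`ctrscore` implements a session-scoring pipeline for this task: a data model
and JSONL I/O for coded, role-tagged transcripts; utterance embedding
backends; two attention-network architectures that map an utterance-vector
sequence (plus optional session metadata) to CTRS predictions; a
frequency-based reference system; therapist-grouped evaluation machinery
with paired bootstrap testing; attention-saliency analysis; and a seeded
synthetic-corpus generator so that every stage is testable without access to
clinical data (which is never distributable).

## Data model and preprocessing

A `session_transcript` holds ordered utterances (`role`, `text`, start/end
seconds), a therapist id, four categorical metadata variables (clinic, level
of care, population, assessment time) and optional `ctrs_scores`. Three
preprocessing rules matter:

* **Talk-turn merging** (`merge_turns`): consecutive same-role utterances
  separated by a silence gap *strictly* shorter than 2 s are merged, texts
  joined with a single space (automatic transcripts carry no reliable
  punctuation, so none is inserted). A gap of exactly 2 s does not merge.
  Merging is idempotent and conserves word counts per role.
* **Role filtering** (`filter_role`): CTRS codes describe therapist
  behavior, so the default pipeline keeps therapist turns only; the
  all-utterance variant is available for comparison. Only the two roles
  therapist/patient are modeled; multi-party (group) sessions are outside
  the data model's scope.
* **Metadata encoding** (`encode_metadata`): each variable becomes a one-hot
  block with one extra reserved *unknown* slot. Cross-validation folds can
  exclude a clinic entirely, so the reserved slot guarantees identical
  train/test dimensions and a well-defined encoding for unseen categories.
  Vocabularies are always built from training folds only.

Totals are recomputed from the 11 codes on construction and never trusted
from a file; binarization uses the clinical threshold of 40 (`high` iff
total ≥ 40).

## Embeddings

Utterances are embedded independently by a pluggable backend: text is
whitespace-tokenized, cropped to the backend's token budget (default 64
tokens — in real corpora only ~2% of utterances are longer), and the
backend's final-layer token vectors are average-pooled. Pooling excludes
special boundary tokens and padding; this is a design choice (the
alternative — pooling over specials too — is exposed as a flag on
`transformer_backend`). Empty utterances map to the zero vector rather than
being dropped, so turn indexing stays aligned with the transcript.

Two backends ship:

* `hash_embed_backend`: every token maps to a fixed pseudo-random unit
  vector keyed by `(token, seed)` through a dedicated Lehmer-PRNG stream
  (the global R RNG is untouched). Distinct tokens get near-orthogonal
  directions, so lexical signal survives mean-pooling. It is deterministic,
  download-free and the default in all tests.
* `transformer_backend`: wraps a `tiny_encoder` (below), pooling its last
  layer.

Session embedding truncates at a cap (256 utterances for therapist-only
input, 512 for all utterances). The default truncation keeps the *first*
`cap` utterances — the simplest deterministic rule; because session endings
carry signal for some codes (homework), a `first_last` variant that keeps
both ends is provided.

## The scoring networks

Both architectures share the encoder: the utterance-vector sequence enters a
single bidirectional GRU layer (64 units per direction by default; update
rule `h_t = (1−z)⊙h_{t−1} + z⊙h̃_t`), and each position's representation is
the concatenation of the forward and backward states (128-dimensional at
defaults). Additive self-attention scores each position as
`v'·tanh(W h_t + b)` through a 10-unit dense layer, softmaxes over valid
positions (padded positions receive −∞ scores, hence exactly zero weight)
and forms a context vector as the weighted average of the hidden states.
The context vector — concatenated with the one-hot metadata vector when
metadata fusion is on — feeds a small MLP (one 20-unit ReLU hidden layer).

* **Single-task** (`arch = "single"`): one attention head, sigmoid output =
  probability of competent delivery. Loss: binary cross-entropy with
  inverse-frequency class weights `w_c = n/(2 n_c)` (the normalization keeps
  the mean weight at 1; only proportionality is essential). The decision
  threshold on the probability is 0.5.
* **Multi-task** (`arch = "multi"`): 11 attention heads over the *shared*
  GRU states, one per code, each with its own MLP and a linear output. The
  metadata vector is concatenated into every head's MLP input. Loss:
  `L = Σ_i L_i`, the sum over codes of per-code batch mean squared error,
  with *unclipped* linear outputs inside the loss; the `[0, 6]` restriction
  is applied only at inference (clipping at evaluation reconciles a linear
  output activation with a bounded code scale without altering training
  gradients). The total is the sum of the 11 clipped predictions and the
  binary label its binarization at 40 — the network never models the total
  directly.

Training uses Adam (initial learning rate 0.001) for at most 200 epochs with
early stopping on validation loss at patience 10; the parameters from the
best-validation epoch are returned. The validation set is carved from the
training material *by therapist* (10% of therapists by default), because the
evaluation protocol is therapist-grouped and an early-stopping signal from
seen therapists would be optimistic. No dropout or weight decay is applied
by default; regularization is left to early stopping (config exposes the
rest of the schedule).

The GRU time loops (forward and backward passes) are implemented as
RcppArmadillo kernels over length-sorted, zero-padded minibatches; the
backward recurrent direction reverses each sequence *within its own valid
length*, so padding stays trailing and the same kernel serves both
directions. All gradients (GRU, attention, MLPs, both losses) are
hand-derived and verified against central finite differences in the test
suite at tolerance 1e-3 (the checks sit away from ReLU kinks, where finite
differences are valid).

## Domain-adaptive pretraining at small scale

The pipeline assumes the embedding backend has been adapted to therapy
language by continued pretraining with masked-token and next-utterance
(pair-order) objectives. The full-scale recipe is recorded as the
`adaptation_config()` defaults — 10,000 steps, learning rate 2e-5,
minibatch 64, a 64-token pair budget, a 0.5 probability of deliberately
short training pairs (transcribed utterances are often short), 15% masking —
but is not exercised by tests; the package trains a `tiny_encoder` instead:

* 2 post-norm transformer blocks of width 32 (2 heads): layer-normalized
  token + position + segment embeddings, residual multi-head attention and
  residual ReLU feed-forward each followed by layer normalization, a
  `tanh`-projected pooler over the `[CLS]` state feeding the pair-order
  head, and a masked-token head tied to the input embedding matrix. The
  normalization layers matter even at this depth: without them the residual
  stream's scale drifts and the pair-order objective trains erratically.
  The full backward pass remains hand-written and
  finite-difference-checked.
* The scaled-down profile (`tiny_adaptation_config()`) runs 500 steps at
  learning rate 3e-3 with batch 32 — a rate suited to a freshly initialized
  small encoder rather than to fine-tuning a large pretrained one.

Instance construction follows the standard recipe: positives are consecutive
utterances within a session (after optional role filtering, under which the
surviving turns count as consecutive — exactly what a therapist-only
adaptation corpus looks like); negatives replace the second segment with a
uniform draw from the corpus, re-drawn if it happens to be the true
successor, at a 50% rate; of the masked tokens 80% become `[MASK]`, 10% a
random vocabulary token, 10% stay unchanged. The train/eval split is at the
*session* level (90/10), so no evaluation utterance can appear in a training
instance. Pair-order accuracy is reported on balanced-by-construction pairs
together with their count; `nsp_accuracy` also accepts a plain function so
oracle and constant reference predictors can be scored identically.

## Reference system

The frequency-based baseline is session-level unigram tf-idf (document =
concatenation of the session's — optionally therapist-only — utterances),
smoothed idf `ln((1+N)/(1+df)) + 1` with L2-normalized rows (the most common
convention; recorded in `TfidfModel$settings`), univariate two-group ANOVA
F-test selection of the 32 best unigrams, and a linear SVM (LIBSVM via
\pkg{e1071}) with inverse-frequency class weights mirroring the neural
models' imbalance handling. Zero-variance features are assigned F = 0 and
can never outrank a positive-F feature; F-statistic ties break toward the
lower column index. All fitting (vocabulary, idf, selection, SVM) happens
inside each training fold only.

## Evaluation protocol

* **Therapist-grouped k-fold** (`grouped_kfold`): all sessions of a
  therapist share a fold (patient identities are unknown, so therapists are
  the grouping unit). Therapists are shuffled by seed and packed
  largest-first into the currently lightest fold — a greedy rule that
  balances session counts; ties go to the lower fold index.
* **Macro-F1**: unweighted mean of per-class F1. A class with no true and no
  predicted members contributes 0 — a deliberate convention that penalizes
  degenerate all-one-class predictors; for binary labels the class space is
  always `{low, high}` regardless of which labels occur.
* **Paired bootstrap** (`paired_bootstrap`): session indices are resampled
  with replacement; per resample `d = F1(A) − F1(B)`; the one-sided p-value
  is the fraction of resamples with `d ≤ 0` (testing "A improves over B";
  identical predictors give exactly p = 1). Implementation note: uniform
  index resampling induces a multinomial distribution over the eight joint
  (truth, A, B) per-session categories, which are sufficient for both
  macro-F1 values, so the counts are drawn directly — distributionally
  identical to naive resampling (the test suite verifies this against a
  literal resampling loop) and exactly invariant to session order.
* **Experiment grid** (`run_experiment_grid`): architecture × metadata ×
  utterance set × backend, all cells under one shared fold assignment so
  comparisons are paired; `marginal_improvements` aggregates each
  technique's mean F1 with and without it and the relative improvement
  `(yes − no)/no`. Metadata vocabularies, tf-idf, and feature selection are
  refit per fold inside every cell.

## Attention saliency

To compare attention across sessions of different lengths, a profile over
`L` utterances is binned onto a fixed grid: utterance `t` (0-indexed)
assigns its weight to bin `⌊t·n_bins/L⌋`, and the result is rescaled by
`n_bins` so the uniform level is 1.0. The mean over bins of any curve is
exactly 1 (mass conservation); pointwise "all bins = 1" for a uniform
profile holds exactly when the bin count divides the session length evenly,
and at the decile level otherwise — decile means are therefore the unit of
analysis. Only held-out (test-fold) profiles are aggregated. For the
multi-task model an additional `mean-of-codes` curve averages the 11
per-code curves. The time axis is utterance index; wall-clock time is a
possible variant not implemented.

## The synthetic corpus generator

`generate_corpus` emulates the statistical structure this method assumes,
with all conditions fixed by `simulation_config()` defaults:

* **Dialogue shape**: total talk turns per session drawn from
  N(430, 230²) clamped to [60, 900] (matching the scale of real coded CBT
  corpora); a role Markov chain with rare same-role repeats puts the
  therapist talk-turn share just under half and exercises turn merging;
  exponential inter-turn gaps produce both mergeable and non-mergeable
  silences; turn lengths are Poisson (mean 10 filler tokens, minimum 3).
* **Latent scores**: for therapist *i*, session *s*, code *c*:
  `score = clamp(round(b + m_s + I_sc + ε_sc), 0, 6)` with
  `I_sc = u_i + d_sc`; defaults `b = 3.25`, therapist skill
  `u_i ~ N(0, 0.8²)`, per-session/per-code deviation `d_sc ~ N(0, 1²)`,
  coder noise `ε ~ N(0, 0.25²)`, and metadata contribution `m_s` summing
  evenly spaced per-category effects with amplitudes 0.12/0.12/0.08/0.15
  per code. Skill is dominant deliberately: competence is largely a
  therapist-level trait, which is also what makes therapist-grouped
  cross-validation the honest protocol. The base level is calibrated so
  roughly a quarter of sessions are `high` (the unbalanced regime of real
  coded corpora); the defaults land in the 20–35% band.
* **Lexical signal**: each code has an invented marker token (e.g.
  `zqagol`), planted into therapist turns at a *rate* per therapist turn
  proportional to `max(0, I_sc + 1.5)` (default 3 markers per 100 turns per
  unit). The rate formulation matters: sessions vary several-fold in length,
  and competence should express as how often skill-relevant language occurs,
  not as an absolute count — absolute counts would be confounded with
  session length for any length-normalized representation. Marker positions
  follow per-code localization: agenda-like early (first 15% of therapist
  turns), homework-like early+late, feedback-like and all remaining codes
  uniform. Patient turns carry only filler vocabulary unless
  `patient_signal = TRUE` deliberately leaks half-strength signal into them
  (for all-utterance experiments). An optional token-substitution rate
  imitates transcription errors.
* **Ground truth** records skills, metadata contributions, latent
  intensities, and the exact marker turn indices, so recovery claims are
  checkable (a self-consistency scan asserts markers in the truth match the
  emitted texts token-for-token).

What passing tests on this corpus do show: that the implementation trains,
generalizes across therapists, fuses metadata profitably when metadata
carries signal orthogonal to text, and localizes per-code attention where
the code's evidence lives. What they do not show: performance on real
therapy language — the generator has no syntax, no topical drift, no coder
idiosyncrasies, and its lexical evidence is far cleaner than word choice in
real sessions. Absolute scores on this corpus say nothing about absolute
scores on clinical data.

Separately, `generate_adjacency_corpus` builds sessions whose consecutive
utterances share rare link tokens, making next-utterance prediction
learnable by token-overlap detection — the testbed for encoder adaptation.

## Problem sizes used by the tests

The shipped test and acceptance runs use the default corpus of 60 therapists
× 10 sessions with the 64-dimensional hash backend, and train the networks
in a scaled-down profile: 32 GRU units per direction, minibatch 32, Adam at
0.002, at most 80 epochs with patience 15, and `first_last` truncation so
session endings survive the 256-utterance cap (the full-scale
64-unit/batch-128/200-epoch recipe remains the `model_config()` default).
Saliency curves aggregate held-out attention pooled across the trained
models of a run, as the reference analysis pools across the fold-models of
its cross-validation. Encoder adaptation runs the tiny 2×32 encoder for 500
steps on a 120-session topical-coherence corpus. Exact-math oracle checks
run on hundreds of small random instances; the bootstrap calibration study
uses 200 repetitions of 2,000 resamples.

## Known limitations

* Two-role dialogues only; group therapy does not fit the data model.
* The embedding backend is frozen during downstream training (feature
  extraction, not fine-tuning), matching the intended design but limiting
  attainable accuracy.
* Attention weights are a localization heuristic, not a causal attribution;
  the saliency analysis is descriptive and no statistical test is attached
  to curve shapes.
* The tiny encoder is a scaled-down stand-in for a large pretrained model;
  it demonstrates the adaptation machinery, not transfer from general
  language.
* Hyperparameters are taken as given; there is no tuning machinery.
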