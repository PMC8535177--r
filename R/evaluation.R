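#' Therapist-grouped k-fold assignment
#'
#' All sessions of a therapist land in one fold, so no therapist appears in
#' both a training and a test fold. Therapists are shuffled by seed, then
#' assigned largest-first to the currently lightest fold (ties to the lower
#' fold index), which balances session counts.
#'
#' @param sessions List of sessions.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return Object of class `ctrs_folds`: `fold_of` (named integer vector,
#'   session_id -> fold in `1..k`), `k`, `therapist_fold`.
#' @export
grouped_kfold <- function(sessions, k = 10L, seed = 1L) {
  ther <- vapply(sessions, `[[`, "", "therapist_id")
  ids <- vapply(sessions, `[[`, "", "session_id")
  ut <- unique(ther)
  if (length(ut) < k)
    stop("need at least k = ", k, " distinct therapists, have ", length(ut))
  set.seed(seed)
  ut <- sample(ut)
  sizes <- vapply(ut, function(t) sum(ther == t), 0L)
  ord <- order(-sizes)   # largest first; stable, so ties keep shuffle order
  loads <- numeric(k)
  tf <- integer(length(ut)); names(tf) <- ut
  for (i in ord) {
    f <- which.min(loads)  # ties resolve to the lower fold index
    tf[[i]] <- f
    loads[[f]] <- loads[[f]] + sizes[[i]]
  }
  fold_of <- tf[ther]
  names(fold_of) <- ids
  structure(list(fold_of = fold_of, k = as.integer(k), therapist_fold = tf),
            class = "ctrs_folds")
}

fold_hash <- function(folds) {
  token_hash(paste(names(folds$fold_of), folds$fold_of, sep = ":",
                   collapse = ";"))
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over the classes of per-class F1 = 2PR/(P+R). A class with
#' no true and no predicted members contributes F1 = 0 (a deliberate
#' convention, documented here because it penalizes degenerate all-one-class
#' predictors).
#'
#' @param y_true,y_pred Label vectors. The class space is the union of
#'   factor levels (so a binary `low`/`high` problem always averages over
#'   both classes, even when a vector is degenerate) or, for bare character
#'   input, the union of observed values.
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(y_true, y_pred) {
  classes <- sort(unique(c(
    if (is.factor(y_true)) levels(y_true) else unique(as.character(y_true)),
    if (is.factor(y_pred)) levels(y_pred) else unique(as.character(y_pred)))))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, 0)
  mean(f1)
}

#' Paired bootstrap test for macro-F1 improvement
#'
#' Resamples session indices with replacement; on each resample computes
#' `d = macroF1(pred_a) - macroF1(pred_b)`. The one-sided p-value is the
#' fraction of resamples with `d <= 0`, testing whether system A improves
#' over reference system B. Identical predictions give `p = 1` exactly.
#'
#' @param y_true True labels; `pred_a`, `pred_b` predictions of the two
#'   systems, all the same length.
#' @param n_resamples Number of bootstrap resamples (reference recipe 1e5).
#' @param seed RNG seed.
#' @return List with `p_value`, `mean_diff` (mean of `d`), `n_resamples`.
#' @export
paired_bootstrap <- function(y_true, pred_a, pred_b, n_resamples = 100000L,
                             seed = 1L) {
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  y <- as.character(y_true) == "high"
  a <- as.character(pred_a) == "high"
  b <- as.character(pred_b) == "high"
  n <- length(y)
  stopifnot(length(a) == n, length(b) == n)
  set.seed(seed)
  # Resampling n session indices uniformly with replacement induces a
  # multinomial draw over the 8 joint (truth, A, B) categories, which are
  # sufficient for both macro-F1 values; drawing the counts directly is
  # distributionally identical, and exactly invariant to session order.
  cat8 <- 4L * y + 2L * a + b
  base_counts <- tabulate(cat8 + 1L, nbins = 8L)
  cnt <- t(stats::rmultinom(n_resamples, n, prob = base_counts / n))
  # count columns are categories 0..7 = (truth, A, B) bits
  yh <- cnt[, 5] + cnt[, 6] + cnt[, 7] + cnt[, 8]
  tp_a <- cnt[, 7] + cnt[, 8]; fp_a <- cnt[, 3] + cnt[, 4]
  fn_a <- yh - tp_a
  tp_b <- cnt[, 6] + cnt[, 8]; fp_b <- cnt[, 2] + cnt[, 4]
  fn_b <- yh - tp_b
  f1 <- function(tp, fp, fn) ifelse(2 * tp + fp + fn > 0,
                                    2 * tp / (2 * tp + fp + fn), 0)
  ma <- (f1(tp_a, fp_a, fn_a) + f1(n - yh - fp_a, fn_a, fp_a)) / 2
  mb <- (f1(tp_b, fp_b, fn_b) + f1(n - yh - fp_b, fn_b, fp_b)) / 2
  d <- ma - mb
  list(p_value = mean(d <= 0), mean_diff = mean(d),
       n_resamples = as.integer(n_resamples))
}

# preprocess one session for a given utterance set: merge talk turns, then
# optionally keep therapist turns only
prep_session <- function(session, utterance_set, merge_gap = 2.0) {
  session$utterances <- merge_turns(session$utterances, merge_gap)
  if (utterance_set == "therapist") session <- filter_role(session, "therapist")
  session
}

#' Therapist-grouped cross-validation of a scoring network
#'
#' For each fold: builds the metadata vocabulary, carves a therapist-disjoint
#' inner validation split for early stopping, embeds the prepared sessions,
#' trains the network and scores the held-out fold. Per-fold refitting of the
#' vocabulary keeps the test fold from influencing any fitted component.
#'
#' @param sessions Labeled sessions (raw transcripts).
#' @param config A [model_config()].
#' @param backend Embedding backend.
#' @param k Folds (ignored when `folds` given).
#' @param seed Fold/shuffle seed.
#' @param utterance_set `"therapist"` or `"all"`.
#' @param folds Optional precomputed [grouped_kfold()] assignment, shared
#'   across paired experiment cells.
#' @param collect_attention Keep each session's test-fold attention profiles
#'   (needed for saliency analysis).
#' @param val_frac Fraction of training-fold therapists held out for early
#'   stopping.
#' @param merge_gap Talk-turn merge threshold in seconds.
#' @return Object of class `ctrs_eval_report`: `per_session` data frame
#'   (session_id, fold, truth, pred, total_pred), `macro_f1`, `config_tag`,
#'   `fold_hash`, optional `attention`.
#' @export
crossvalidate_model <- function(sessions, config, backend, k = 10L, seed = 1L,
                                utterance_set = c("therapist", "all"),
                                folds = NULL, collect_attention = FALSE,
                                val_frac = 0.1, merge_gap = 2.0) {
  utterance_set <- match.arg(utterance_set)
  check_labeled(sessions, "cross-validation corpus")
  if (is.null(folds)) folds <- grouped_kfold(sessions, k, seed)
  prepped <- lapply(sessions, prep_session, utterance_set = utterance_set,
                    merge_gap = merge_gap)
  ids <- vapply(sessions, `[[`, "", "session_id")
  fold_idx <- folds$fold_of[ids]
  rows <- list(); attention <- list()
  for (f in sort(unique(fold_idx))) {
    tr_raw <- sessions[fold_idx != f]
    te <- prepped[fold_idx == f]
    # leakage guard: therapist sets must be disjoint by construction
    stopifnot(length(intersect(
      vapply(tr_raw, `[[`, "", "therapist_id"),
      vapply(prepped[fold_idx == f], `[[`, "", "therapist_id"))) == 0L)
    vocab <- build_metadata_vocab(tr_raw)
    tr_prep <- prepped[fold_idx != f]
    sp <- make_splits(tr_prep, c(train = 1 - val_frac, val = val_frac),
                      seed = seed + f)
    emb_tr <- embed_corpus(sp$train, backend, config$seq_cap, vocab)
    emb_va <- embed_corpus(sp$val, backend, config$seq_cap, vocab)
    emb_te <- embed_corpus(te, backend, config$seq_cap, vocab)
    fit <- train_model(config, emb_tr, emb_va)
    preds <- predict_sessions(fit, emb_te)
    for (p in preds) {
      rows[[p$session_id]] <- data.frame(
        session_id = p$session_id, fold = f,
        truth = as.character(binarize_total(
          sessions[[which(ids == p$session_id)]]$labels$total)),
        pred = as.character(p$label_pred),
        total_pred = if (is.null(p$total_pred)) NA_real_ else p$total_pred,
        stringsAsFactors = FALSE)
      if (collect_attention) attention[[p$session_id]] <- p$attention
    }
  }
  per_session <- do.call(rbind, rows[ids])
  structure(list(per_session = per_session,
                 macro_f1 = macro_f1(factor(per_session$truth, c("low", "high")),
                                     factor(per_session$pred, c("low", "high"))),
                 config_tag = list(arch = config$arch,
                                   use_metadata = config$use_metadata,
                                   utterance_set = utterance_set,
                                   backend = backend$name),
                 fold_hash = fold_hash(folds),
                 folds = folds,
                 attention = if (collect_attention) attention),
            class = "ctrs_eval_report")
}

#' @export
print.ctrs_eval_report <- function(x, ...) {
  tag <- x$config_tag
  cat("<ctrs_eval_report> ", tag$arch, "-task | metadata ",
      if (isTRUE(tag$use_metadata)) "yes" else "no", " | ",
      tag$utterance_set, " utterances | ", tag$backend, "\n",
      "  sessions: ", nrow(x$per_session), "  macro-F1: ",
      format(x$macro_f1, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cross-validate the tf-idf baseline under the same folds
#'
#' @inheritParams crossvalidate_model
#' @param k_features Number of F-test-selected unigrams.
#' @return A `ctrs_eval_report`.
#' @export
crossvalidate_baseline <- function(sessions, k = 10L, seed = 1L,
                                   utterance_set = c("therapist", "all"),
                                   folds = NULL, k_features = 32L,
                                   merge_gap = 2.0) {
  utterance_set <- match.arg(utterance_set)
  check_labeled(sessions, "cross-validation corpus")
  if (is.null(folds)) folds <- grouped_kfold(sessions, k, seed)
  prepped <- lapply(sessions, prep_session, utterance_set = "all",
                    merge_gap = merge_gap)
  role <- if (utterance_set == "therapist") "therapist" else NULL
  ids <- vapply(sessions, `[[`, "", "session_id")
  fold_idx <- folds$fold_of[ids]
  rows <- list()
  for (f in sort(unique(fold_idx))) {
    fit <- fit_baseline(prepped[fold_idx != f], role_filter = role,
                        k = k_features)
    te <- prepped[fold_idx == f]
    pred <- predict(fit, te)
    truth <- binarize_total(vapply(te, function(s) s$labels$total, 0L))
    for (j in seq_along(te))
      rows[[te[[j]]$session_id]] <- data.frame(
        session_id = te[[j]]$session_id, fold = f,
        truth = as.character(truth[[j]]), pred = as.character(pred[[j]]),
        total_pred = NA_real_, stringsAsFactors = FALSE)
  }
  per_session <- do.call(rbind, rows[ids])
  structure(list(per_session = per_session,
                 macro_f1 = macro_f1(factor(per_session$truth, c("low", "high")),
                                     factor(per_session$pred, c("low", "high"))),
                 config_tag = list(arch = "baseline", use_metadata = FALSE,
                                   utterance_set = utterance_set,
                                   backend = "tfidf"),
                 fold_hash = fold_hash(folds), folds = folds,
                 attention = NULL),
            class = "ctrs_eval_report")
}

#' Run the full experiment grid
#'
#' Crosses architecture x metadata x utterance set x embedding backend with a
#' single shared fold assignment, so all cells are paired and directly
#' comparable.
#'
#' @param sessions Labeled sessions.
#' @param base_config [model_config()] template; `arch`, `use_metadata`,
#'   `seq_cap` and `batch_size` are overridden per cell.
#' @param backends Named list of embedding backends.
#' @param k,seed Fold parameters.
#' @param archs,metadata_opts,utterance_sets Grid axes.
#' @param seq_caps,batch_sizes Named (`therapist`, `all`) per-utterance-set
#'   settings.
#' @param collect_attention Keep test-fold attention profiles per cell.
#' @return List of `ctrs_eval_report`, one per grid cell; all share the same
#'   `fold_hash`.
#' @export
run_experiment_grid <- function(sessions, base_config,
                                backends = list(hash = hash_embed_backend()),
                                k = 10L, seed = 1L,
                                archs = c("single", "multi"),
                                metadata_opts = c(FALSE, TRUE),
                                utterance_sets = c("all", "therapist"),
                                seq_caps = c(therapist = 256L, all = 512L),
                                batch_sizes = c(therapist = 128L, all = 64L),
                                collect_attention = FALSE) {
  folds <- grouped_kfold(sessions, k, seed)
  grid <- expand.grid(arch = archs, use_metadata = metadata_opts,
                      utterance_set = utterance_sets,
                      backend = names(backends),
                      stringsAsFactors = FALSE)
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- base_config
    cfg$arch <- g$arch
    cfg$use_metadata <- g$use_metadata
    cfg$seq_cap <- as.integer(seq_caps[[g$utterance_set]])
    cfg$batch_size <- as.integer(batch_sizes[[g$utterance_set]])
    reports[[i]] <- crossvalidate_model(
      sessions, cfg, backends[[g$backend]], seed = seed,
      utterance_set = g$utterance_set, folds = folds,
      collect_attention = collect_attention)
  }
  names(reports) <- apply(grid, 1L, paste, collapse = "|")
  reports
}

#' Marginal contribution of each technique across grid cells
#'
#' For every grid axis with two settings, the mean macro-F1 over cells with
#' the technique applied vs. not, and the relative improvement
#' `(yes - no) / no`.
#'
#' @param reports List of `ctrs_eval_report` from [run_experiment_grid()].
#' @return Data frame with columns `technique`, `no`, `yes`,
#'   `relative_improvement`.
#' @export
marginal_improvements <- function(reports) {
  tag <- function(r, f) r$config_tag[[f]]
  f1 <- vapply(reports, `[[`, 0, "macro_f1")
  axes <- list(
    multi_task = vapply(reports, function(r) tag(r, "arch") == "multi", TRUE),
    metadata = vapply(reports, function(r) isTRUE(tag(r, "use_metadata")), TRUE),
    only_therapist = vapply(reports, function(r)
      tag(r, "utterance_set") == "therapist", TRUE))
  bk <- vapply(reports, function(r) tag(r, "backend"), "")
  if (length(unique(bk)) == 2L)
    axes$adapted_backend <- bk == sort(unique(bk))[[2L]]
  do.call(rbind, lapply(names(axes), function(ax) {
    yes <- mean(f1[axes[[ax]]]); no <- mean(f1[!axes[[ax]]])
    data.frame(technique = ax, no = no, yes = yes,
               relative_improvement = (yes - no) / no)
  }))
}
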