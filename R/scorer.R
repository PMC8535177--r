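#' Fit a session-level CBT competence scorer
#'
#' The main entry point: takes labeled session transcripts and fits the
#' attention network end to end — talk-turn merging, optional restriction to
#' therapist utterances, utterance embedding through the chosen backend,
#' metadata one-hot encoding, then training of the bidirectional GRU +
#' additive attention architecture with early stopping on a
#' therapist-disjoint validation split.
#'
#' With `arch = "multi"` the scorer regresses all 11 CTRS codes (one
#' attention head and output MLP per code) and classifies a session as
#' competent when the summed, `[0, 6]`-clipped code predictions reach the
#' clinical threshold of 40. With `arch = "single"` it predicts the binary
#' competence label directly through one head and a sigmoid, trained with
#' inverse-frequency class-weighted cross-entropy.
#'
#' @param sessions List of labeled [session_transcript()] objects.
#' @param arch `"multi"` (default) or `"single"`.
#' @param backend Embedding backend (default: 64-dimensional
#'   [hash_embed_backend()]; see also [transformer_backend()]).
#' @param utterance_set `"therapist"` (default) or `"all"`.
#' @param use_metadata Fuse the one-hot session metadata into every output
#'   head.
#' @param val_frac Fraction of therapists held out for early stopping.
#' @param merge_gap Talk-turn merge threshold in seconds.
#' @param seed Seed for the validation split and network training.
#' @param ... Further arguments to [model_config()] (e.g. `max_epochs`,
#'   `recurrent_units`, `seq_cap`).
#' @return An object of class `ctrs_scorer` with methods [print()],
#'   [summary()], [predict()], [plot()], [fitted()] and [residuals()].
#' @examples
#' corpus <- generate_corpus(simulation_config(n_therapists = 12,
#'                                             sessions_per_therapist = 2,
#'                                             turns_mean = 60, turns_sd = 10,
#'                                             seed = 7))
#' fit <- ctrs_scorer(corpus$sessions, max_epochs = 3, recurrent_units = 8,
#'                    seq_cap = 32, batch_size = 8)
#' fit
#' head(predict(fit, corpus$sessions[1:2]))
#' @export
ctrs_scorer <- function(sessions, arch = c("multi", "single"),
                        backend = hash_embed_backend(),
                        utterance_set = c("therapist", "all"),
                        use_metadata = TRUE, val_frac = 0.1, merge_gap = 2.0,
                        seed = 1L, ...) {
  arch <- match.arg(arch)
  utterance_set <- match.arg(utterance_set)
  check_labeled(sessions, "training corpus")
  extra <- list(...)
  if (is.null(extra$seq_cap))
    extra$seq_cap <- if (utterance_set == "therapist") 256L else 512L
  if (is.null(extra$batch_size))
    extra$batch_size <- if (utterance_set == "therapist") 128L else 64L
  config <- do.call(model_config, c(list(arch = arch,
                                         use_metadata = use_metadata,
                                         seed = seed), extra))
  prepped <- lapply(sessions, prep_session, utterance_set = utterance_set,
                    merge_gap = merge_gap)
  vocab <- build_metadata_vocab(sessions)
  sp <- make_splits(prepped, c(train = 1 - val_frac, val = val_frac),
                    seed = seed)
  emb_tr <- embed_corpus(sp$train, backend, config$seq_cap, vocab)
  emb_va <- embed_corpus(sp$val, backend, config$seq_cap, vocab)
  model <- train_model(config, emb_tr, emb_va)

  fit_preds <- predict_sessions(model, c(emb_tr, emb_va))
  truth <- lapply(c(sp$train, sp$val), function(s) s$labels)
  names(truth) <- names(fit_preds)
  structure(list(model = model, backend = backend, vocab = vocab,
                 utterance_set = utterance_set, merge_gap = merge_gap,
                 fitted_predictions = fit_preds, fitted_truth = truth,
                 n_sessions = length(sessions)),
            class = "ctrs_scorer")
}

prediction_frame <- function(preds) {
  multi <- !is.null(preds[[1L]]$code_preds)
  df <- data.frame(session_id = vapply(preds, `[[`, "", "session_id"),
                   stringsAsFactors = FALSE)
  if (multi) {
    for (code in CTRS_CODES)
      df[[code]] <- vapply(preds, function(p) p$code_preds[[code]], 0)
    df$total_pred <- vapply(preds, `[[`, 0, "total_pred")
  } else {
    df$prob_high <- vapply(preds, `[[`, 0, "prob_high")
  }
  df$label_pred <- factor(vapply(preds, function(p)
    as.character(p$label_pred), ""), levels = c("low", "high"))
  rownames(df) <- NULL
  df
}

#' Score new sessions with a fitted scorer
#'
#' @param object A `ctrs_scorer`.
#' @param newdata List of [session_transcript()] objects (labels optional).
#' @param attention Attach the per-session attention profiles as the
#'   `"attention"` attribute of the result.
#' @param ... Unused.
#' @return Data frame with one row per session: predicted codes and total
#'   (multi-task) or `prob_high` (single-task), plus the `low`/`high` label.
#' @export
predict.ctrs_scorer <- function(object, newdata, attention = FALSE, ...) {
  prepped <- lapply(newdata, prep_session,
                    utterance_set = object$utterance_set,
                    merge_gap = object$merge_gap)
  emb <- embed_corpus(prepped, object$backend, object$model$config$seq_cap,
                      object$vocab)
  preds <- predict_sessions(object$model, emb)
  df <- prediction_frame(preds)
  if (attention)
    attr(df, "attention") <- lapply(preds, `[[`, "attention")
  df
}

#' @export
print.ctrs_scorer <- function(x, ...) {
  cfg <- x$model$config
  cat("<ctrs_scorer> ", cfg$arch, "-task CTRS scorer\n",
      "  ", x$n_sessions, " training sessions (", x$utterance_set,
      " utterances, backend ", x$backend$name, ")\n",
      "  GRU ", cfg$recurrent_units, "x2 | attention ", n_heads(cfg),
      " head(s) x ", cfg$attention_hidden, " | metadata ",
      if (cfg$use_metadata) "fused" else "off", "\n",
      "  stopped after ", nrow(x$model$history), " epochs (best epoch ",
      x$model$best_epoch, ", val loss ",
      format(min(x$model$history$val_loss), digits = 5), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.ctrs_scorer <- function(object, ...) {
  df <- prediction_frame(object$fitted_predictions)
  truth_tot <- vapply(object$fitted_truth[df$session_id], `[[`, 0L, "total")
  truth_lab <- binarize_total(truth_tot)
  out <- list(config = object$model$config,
              history = object$model$history,
              train_macro_f1 = macro_f1(truth_lab, df$label_pred))
  if (!is.null(df$total_pred)) {
    out$total_cor <- cor(df$total_pred, truth_tot)
    codes_true <- t(vapply(object$fitted_truth[df$session_id],
                           function(l) as.numeric(l$codes), numeric(11L)))
    out$code_rmse <- sqrt(colMeans((as.matrix(df[, CTRS_CODES]) -
                                      codes_true)^2))
  }
  class(out) <- "summary.ctrs_scorer"
  out
}

#' @export
print.summary.ctrs_scorer <- function(x, ...) {
  cat("CTRS scorer (", x$config$arch, "-task)\n", sep = "")
  cat("  epochs run: ", nrow(x$history), "  final val loss: ",
      format(tail(x$history$val_loss, 1), digits = 5), "\n", sep = "")
  cat("  training-set macro-F1: ", format(x$train_macro_f1, digits = 4),
      "\n", sep = "")
  if (!is.null(x$total_cor)) {
    cat("  corr(predicted total, true total): ",
        format(x$total_cor, digits = 4), "\n  per-code RMSE:\n", sep = "")
    print(round(x$code_rmse, 3))
  }
  invisible(x)
}

#' Fitted predictions on the training corpus
#' @param object A `ctrs_scorer`.
#' @param ... Unused.
#' @return Prediction data frame as in [predict.ctrs_scorer()].
#' @export
fitted.ctrs_scorer <- function(object, ...) {
  prediction_frame(object$fitted_predictions)
}

#' Training-set residuals
#'
#' Multi-task: true minus predicted code scores (one column per code) plus
#' the total residual. Single-task: binary label minus predicted
#' probability.
#'
#' @param object A `ctrs_scorer`.
#' @param ... Unused.
#' @return Data frame of residuals keyed by session_id.
#' @export
residuals.ctrs_scorer <- function(object, ...) {
  df <- prediction_frame(object$fitted_predictions)
  truth <- object$fitted_truth[df$session_id]
  out <- data.frame(session_id = df$session_id, stringsAsFactors = FALSE)
  if (!is.null(df$total_pred)) {
    for (code in CTRS_CODES)
      out[[code]] <- vapply(truth, function(l) l$codes[[code]], 0L) -
        df[[code]]
    out$total <- vapply(truth, `[[`, 0L, "total") - df$total_pred
  } else {
    y <- as.numeric(binarize_total(vapply(truth, `[[`, 0L, "total")) == "high")
    out$residual <- y - df$prob_high
  }
  out
}

#' Plot training history or attention saliency of a fitted scorer
#'
#' @param x A `ctrs_scorer`.
#' @param which `"history"` (train/validation loss per epoch) or
#'   `"saliency"` (mean attention curves over the training corpus).
#' @param heads Head ids for the saliency panel.
#' @param ... Passed to the underlying plot.
#' @export
plot.ctrs_scorer <- function(x, which = c("history", "saliency"),
                             heads = c("ag", "fb", "hw", "total"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$model$history
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = 1, lwd = 2, col = c("grey40", "firebrick"),
                      xlab = "epoch", ylab = "loss", ...)
    graphics::legend("topright", c("train", "validation"),
                     col = c("grey40", "firebrick"), lty = 1, lwd = 2,
                     bty = "n")
  } else {
    sal <- aggregate_saliency(lapply(x$fitted_predictions, `[[`, "attention"))
    plot(sal, heads = heads, ...)
  }
  invisible(x)
}
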