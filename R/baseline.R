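#' Fit a session-level unigram tf-idf model
#'
#' Each session's document is the concatenation of its (optionally
#' role-filtered) utterance texts. Uses the common smoothed convention
#' `idf = ln((1 + N) / (1 + df)) + 1` with L2-normalized rows; the
#' conventions in force are recorded in `settings`.
#'
#' @param sessions List of [session_transcript()] objects (training folds
#'   only — the fitted vocabulary and idf must never see test documents).
#' @param role_filter Optional `"therapist"`/`"patient"` restriction.
#' @param lowercase Lowercase tokens before counting.
#' @param sublinear_tf Use `1 + log(tf)` instead of raw counts.
#' @return Object of class `ctrs_tfidf`: `vocabulary` (token -> column),
#'   `idf`, `settings`.
#' @export
fit_tfidf <- function(sessions, role_filter = NULL, lowercase = TRUE,
                      sublinear_tf = FALSE) {
  docs <- session_documents(sessions, role_filter, lowercase)
  vocab <- sort(unique(unlist(docs)))
  if (!length(vocab)) stop("empty vocabulary: no tokens in corpus")
  df <- numeric(length(vocab))
  names(df) <- vocab
  for (d in docs) {
    u <- unique(d)
    df[u] <- df[u] + 1
  }
  idf <- log((1 + length(docs)) / (1 + df)) + 1
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 idf = idf,
                 settings = list(lowercase = lowercase,
                                 sublinear_tf = sublinear_tf,
                                 role_filter = role_filter)),
            class = "ctrs_tfidf")
}

session_documents <- function(sessions, role_filter, lowercase) {
  lapply(sessions, function(s) {
    if (!is.null(role_filter)) s <- filter_role(s, role_filter)
    txt <- paste(vapply(s$utterances, `[[`, "", "text"), collapse = " ")
    if (lowercase) txt <- tolower(txt)
    tokenize_crop(txt, max_tokens = .Machine$integer.max)
  })
}

#' Transform sessions into the fitted tf-idf feature space
#'
#' Tokens outside the training vocabulary are ignored.
#'
#' @param model A fitted `ctrs_tfidf`.
#' @param sessions List of sessions.
#' @return Dense numeric matrix `length(sessions) x |vocabulary|` with
#'   L2-normalized rows.
#' @export
transform_tfidf <- function(model, sessions) {
  docs <- session_documents(sessions, model$settings$role_filter,
                            model$settings$lowercase)
  X <- matrix(0, length(docs), length(model$vocabulary),
              dimnames = list(NULL, names(model$vocabulary)))
  for (i in seq_along(docs)) {
    tab <- table(docs[[i]])
    tab <- tab[names(tab) %in% names(model$vocabulary)]
    if (!length(tab)) next
    tf <- as.numeric(tab)
    if (model$settings$sublinear_tf) tf <- 1 + log(tf)
    X[i, names(tab)] <- tf * model$idf[names(tab)]
    nrm <- sqrt(sum(X[i, ]^2))
    if (nrm > 0) X[i, ] <- X[i, ] / nrm
  }
  X
}

#' Select the k best features by one-way ANOVA F statistic
#'
#' For each column, the univariate F statistic between the two label groups:
#' between-group mean square over within-group mean square. A zero-variance
#' feature has `F = 0` by convention and is never selected ahead of any
#' feature with positive F; a feature perfectly separating the groups with
#' zero within-group variance has infinite F and ranks first. Ties break
#' toward the lower column index.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1, logical, or factor `low`/`high`).
#' @param k Number of features to keep (default 32).
#' @return Integer vector of `k` column indices, best first.
#' @export
select_k_best_ftest <- function(X, y, k = 32L) {
  if (is.factor(y)) y <- as.numeric(y == "high")
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), k <= ncol(X))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  f <- ftest_statistics(X, y)
  order(-f)[seq_len(k)]   # stable order: ties keep lower column index
}

# vectorized one-way (two-group) ANOVA F per column
ftest_statistics <- function(X, y) {
  n <- nrow(X)
  i1 <- y == 1; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m0 <- colMeans(X[i0, , drop = FALSE])
  m <- colMeans(X)
  between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  within <- colSums((X[i1, , drop = FALSE] -
                       rep(m1, each = n1))^2) +
    colSums((X[i0, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- ifelse(within > 0, (between / 1) / (within / (n - 2)),
              ifelse(between > 0, Inf, 0))
  f[between == 0 & within == 0] <- 0  # zero-variance convention
  f
}

#' Train a linear support-vector classifier on selected features
#'
#' Thin wrapper over the LIBSVM linear machine in \pkg{e1071}, with optional
#' inverse-frequency class weighting mirroring the neural models' imbalance
#' handling.
#'
#' @param X_selected Numeric matrix of selected features.
#' @param y Labels (factor `low`/`high`, or binary coercible).
#' @param class_weighting Weight classes inversely to frequency.
#' @param cost SVM cost parameter.
#' @return Object of class `ctrs_svm` with a [predict()] method returning a
#'   `low`/`high` factor.
#' @export
train_svm <- function(X_selected, y, class_weighting = TRUE, cost = 1) {
  if (!is.factor(y))
    y <- factor(ifelse(as.numeric(y) == 1, "high", "low"),
                levels = c("low", "high"))
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("both classes must be present in training labels")
  y <- factor(y, levels = c("low", "high"))
  cw <- if (class_weighting) {
    w <- class_weights(y)
    c(low = unname(w["low"]), high = unname(w["high"]))
  } else NULL
  fit <- e1071::svm(x = X_selected, y = y, kernel = "linear", cost = cost,
                    scale = FALSE, class.weights = cw)
  structure(list(fit = fit), class = "ctrs_svm")
}

#' @export
predict.ctrs_svm <- function(object, newdata, ...) {
  factor(as.character(predict(object$fit, newdata)), levels = c("low", "high"))
}

#' Fit the full frequency-based reference system
#'
#' tf-idf on the training sessions, univariate F-test selection of the `k`
#' best unigrams against the binarized competence label, then a linear SVM.
#'
#' @param train_sessions Labeled training sessions.
#' @param role_filter Optional role restriction (therapist-only baseline).
#' @param k Number of selected features.
#' @param class_weighting Passed to [train_svm()].
#' @return Object of class `ctrs_baseline` with a [predict()] method taking
#'   raw sessions, plus a `features` data frame (token, F statistic, rank).
#' @export
fit_baseline <- function(train_sessions, role_filter = NULL, k = 32L,
                         class_weighting = TRUE) {
  check_labeled(train_sessions, "baseline training set")
  y <- binarize_total(vapply(train_sessions, function(s) s$labels$total, 0L))
  tfidf <- fit_tfidf(train_sessions, role_filter)
  X <- transform_tfidf(tfidf, train_sessions)
  k <- min(k, ncol(X))
  sel <- select_k_best_ftest(X, y, k)
  f <- ftest_statistics(X, as.numeric(y == "high"))
  svm <- train_svm(X[, sel, drop = FALSE], y, class_weighting)
  structure(list(tfidf = tfidf, selected = sel, svm = svm,
                 features = data.frame(token = colnames(X)[sel],
                                       f_statistic = f[sel],
                                       rank = seq_along(sel))),
            class = "ctrs_baseline")
}

#' @export
predict.ctrs_baseline <- function(object, newdata, ...) {
  X <- transform_tfidf(object$tfidf, newdata)
  predict(object$svm, X[, object$selected, drop = FALSE])
}

#' Write the selected-feature report of a fitted baseline
#'
#' @param baseline A `ctrs_baseline`.
#' @param path CSV output path.
#' @return The report data frame, invisibly.
#' @export
write_feature_report <- function(baseline, path) {
  write.csv(baseline$features, path, row.names = FALSE)
  invisible(baseline$features)
}
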