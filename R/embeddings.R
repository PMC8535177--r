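#' Whitespace tokenization with a fixed crop
#'
#' Splits on runs of whitespace and keeps the first `max_tokens` tokens.
#' In real transcript corpora only a small tail of utterances (about 2%)
#' exceeds a 64-token budget, so a hard crop loses little.
#'
#' @param text A single string; `""` gives an empty token vector.
#' @param max_tokens Crop length (default 64).
#' @return Character vector of at most `max_tokens` tokens.
#' @export
tokenize_crop <- function(text, max_tokens = 64L) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  head(toks, max_tokens)
}

# -- deterministic token hashing / PRNG (independent of R's global RNG) ------

HASH_MOD <- 2147483647  # 2^31 - 1, Park-Miller modulus

token_hash <- function(token) {
  h <- 7
  for (b in utf8ToInt(token)) h <- (h * 31 + b) %% HASH_MOD
  h
}

# Lehmer LCG stream of standard normals keyed by an integer state
hash_normals <- function(state, n) {
  x <- (state %% (HASH_MOD - 1)) + 1
  u <- numeric(n)
  for (i in seq_len(n)) {
    x <- (16807 * x) %% HASH_MOD
    u[[i]] <- x / HASH_MOD
  }
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Deterministic hash embedding backend
#'
#' Maps every whitespace token to a fixed pseudo-random unit vector keyed by
#' `(token, seed)`; an utterance embeds as the mean of its token vectors.
#' The backend is hermetic (no model download, no global-RNG side effects)
#' and identical input always yields identical vectors, which makes it the
#' default backend for tests and simulations: distinct tokens get
#' near-orthogonal directions, so lexical signal survives pooling.
#'
#' @param dimension Embedding dimension (default 64).
#' @param seed Integer key mixed into every token hash.
#' @param max_tokens Tokenization crop (default 64).
#' @return An object of class `c("hash_backend", "ctrs_backend")` with fields
#'   `name`, `dimension`, `max_tokens` and an internal token-vector cache.
#' @export
hash_embed_backend <- function(dimension = 64L, seed = 1L, max_tokens = 64L) {
  stopifnot(dimension >= 1, max_tokens >= 1)
  cache <- new.env(parent = emptyenv())
  structure(list(name = sprintf("hash%d-s%d", dimension, seed),
                 dimension = as.integer(dimension), seed = as.integer(seed),
                 max_tokens = as.integer(max_tokens), cache = cache),
            class = c("hash_backend", "ctrs_backend"))
}

hash_token_vector <- function(backend, token) {
  v <- backend$cache[[token]]
  if (is.null(v)) {
    state <- (token_hash(token) * 97 + backend$seed * 10007) %% HASH_MOD
    z <- hash_normals(state, backend$dimension)
    v <- z / sqrt(sum(z^2))
    backend$cache[[token]] <- v
  }
  v
}

#' Embed token sequences with a backend
#'
#' Generic over backend classes; returns one row per token.
#' @param backend A `ctrs_backend`.
#' @param tokens Character vector of tokens.
#' @return Numeric matrix `length(tokens) x dimension`.
#' @export
embed_tokens <- function(backend, tokens) UseMethod("embed_tokens")

#' @export
embed_tokens.hash_backend <- function(backend, tokens) {
  if (!length(tokens)) return(matrix(0, 0L, backend$dimension))
  do.call(rbind, lapply(tokens, hash_token_vector, backend = backend))
}

#' Embed one utterance as a fixed-dimension vector
#'
#' Tokenizes with [tokenize_crop()] at the backend's token budget and
#' average-pools the backend's final-layer token representations, excluding
#' padding and special boundary tokens. An empty utterance maps to the zero
#' vector (rather than being dropped) so turn indexing stays aligned with the
#' transcript.
#'
#' @param text A single string.
#' @param backend A `ctrs_backend` (e.g. [hash_embed_backend()] or
#'   [transformer_backend()]).
#' @return Numeric vector of length `backend$dimension`.
#' @export
embed_utterance <- function(text, backend) {
  toks <- tokenize_crop(text, backend$max_tokens)
  if (!length(toks)) return(numeric(backend$dimension))
  colMeans(embed_tokens(backend, toks))
}

#' Embed a whole session
#'
#' Embeds the session's utterances in order (after whatever merging/filtering
#' the caller applied), truncated at `cap` utterances, and attaches the
#' one-hot metadata vector.
#'
#' @param session A [session_transcript()] with at least one utterance.
#' @param backend A `ctrs_backend`.
#' @param cap Maximum number of utterances kept (256 for therapist-only
#'   pipelines, 512 when all utterances are used).
#' @param vocab Metadata vocabulary from [build_metadata_vocab()], or `NULL`
#'   to skip metadata encoding.
#' @param truncation `"first"` keeps the first `cap` utterances;
#'   `"first_last"` keeps the first half of the budget from the start and the
#'   second half from the end, since session endings carry signal for some
#'   codes.
#' @return An object of class `ctrs_embedded`: `session_id`, `vectors`
#'   (`L x dimension` matrix, `L = min(#utterances, cap)`), `metadata_vec`,
#'   `labels`, `n_utterances` (pre-truncation count).
#' @export
embed_session <- function(session, backend, cap = 256L, vocab = NULL,
                          truncation = c("first", "first_last")) {
  truncation <- match.arg(truncation)
  n <- length(session$utterances)
  if (n == 0L) stop("session ", session$session_id, " has no utterances to encode")
  keep <- if (n <= cap) seq_len(n) else switch(truncation,
    first = seq_len(cap),
    first_last = c(seq_len(ceiling(cap / 2)),
                   seq.int(n - floor(cap / 2) + 1L, n)))
  texts <- vapply(session$utterances[keep], `[[`, "", "text")
  vecs <- do.call(rbind, lapply(texts, embed_utterance, backend = backend))
  structure(list(session_id = session$session_id,
                 therapist_id = session$therapist_id,
                 vectors = vecs,
                 metadata_vec = if (is.null(vocab)) numeric(0) else
                   encode_metadata(session$metadata, vocab),
                 labels = session$labels,
                 n_utterances = n),
            class = "ctrs_embedded")
}

#' Embed a list of sessions
#'
#' Convenience wrapper applying [embed_session()] to each element, with a
#' token-level cache shared through the backend.
#'
#' @inheritParams embed_session
#' @param sessions List of sessions.
#' @return List of `ctrs_embedded` objects.
#' @export
embed_corpus <- function(sessions, backend, cap = 256L, vocab = NULL,
                         truncation = "first") {
  lapply(sessions, embed_session, backend = backend, cap = cap,
         vocab = vocab, truncation = truncation)
}
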