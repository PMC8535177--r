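#' @useDynLib ctrscore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rpois sd cor predict quantile
#' @importFrom utils head tail write.csv
NULL

CTRS_CODES <- c("ag", "fb", "un", "ip", "co", "pt", "gd", "cb", "sc", "at", "hw")

METADATA_FIELDS <- c("clinic", "level_of_care", "population", "assessment_time")

#' The eleven CTRS code abbreviations
#'
#' Agenda, feedback, understanding, interpersonal effectiveness,
#' collaboration, pacing, guided discovery, key cognitions & behaviors,
#' strategy for change, application of techniques, homework.
#'
#' @return Character vector of the 11 code abbreviations, in canonical order.
#' @export
ctrs_code_names <- function() CTRS_CODES

#' Construct a single utterance
#'
#' @param role `"therapist"` or `"patient"`.
#' @param text Utterance text (possibly empty).
#' @param start_s,end_s Start/end time in seconds, `end_s >= start_s >= 0`.
#' @return An object of class `ctrs_utterance`.
#' @export
utterance <- function(role, text, start_s, end_s) {
  role <- match.arg(role, c("therapist", "patient"))
  if (!is.character(text) || length(text) != 1L)
    stop("`text` must be a single string")
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (is.na(start_s) || is.na(end_s) || start_s < 0 || end_s < start_s)
    stop("utterance times must satisfy 0 <= start_s <= end_s")
  structure(list(role = role, text = text, start_s = start_s, end_s = end_s),
            class = "ctrs_utterance")
}

#' Construct session-level metadata
#'
#' Four categorical descriptors of the session context: the clinic, the level
#' of care, the population served, and the assessment time relative to the
#' therapist's training. Values are free strings; encoding against a known
#' vocabulary (with an unknown fallback slot) happens in [encode_metadata()].
#'
#' @param clinic,level_of_care,population,assessment_time Single strings.
#' @return An object of class `ctrs_metadata`.
#' @export
session_metadata <- function(clinic = "unknown", level_of_care = "unknown",
                             population = "unknown", assessment_time = "unknown") {
  vals <- list(clinic = clinic, level_of_care = level_of_care,
               population = population, assessment_time = assessment_time)
  for (f in METADATA_FIELDS)
    if (!is.character(vals[[f]]) || length(vals[[f]]) != 1L || is.na(vals[[f]]))
      stop("metadata field `", f, "` must be a single string")
  structure(vals, class = "ctrs_metadata")
}

#' Construct a CTRS score set
#'
#' @param codes Named numeric vector or list covering all 11 code
#'   abbreviations (see [ctrs_code_names()]), each on the 0-6 Likert scale.
#' @return An object of class `ctrs_scores` with elements `codes` (named
#'   integer vector in canonical order) and `total` (their sum). The total is
#'   always recomputed from the codes, never taken from input.
#' @export
ctrs_scores <- function(codes) {
  codes <- unlist(codes)
  if (!all(CTRS_CODES %in% names(codes)))
    stop("codes must name all 11 CTRS abbreviations: ",
         paste(setdiff(CTRS_CODES, names(codes)), collapse = ", "), " missing")
  codes <- codes[CTRS_CODES]
  if (any(is.na(codes)) || any(codes < 0 | codes > 6) || any(codes != round(codes)))
    stop("each CTRS code must be an integer in [0, 6]")
  codes <- as.integer(round(codes))
  names(codes) <- CTRS_CODES
  structure(list(codes = codes, total = sum(codes)), class = "ctrs_scores")
}

#' Construct a session transcript
#'
#' The unit of prediction: an ordered, role-tagged utterance sequence plus the
#' therapist identifier, session metadata and (optionally) CTRS labels.
#'
#' @param session_id,therapist_id Single strings.
#' @param utterances List of [utterance()] objects sorted by start time.
#' @param metadata A [session_metadata()] object.
#' @param labels A [ctrs_scores()] object, or `NULL` for unlabeled sessions.
#' @return An object of class `ctrs_session`.
#' @export
session_transcript <- function(session_id, therapist_id, utterances,
                               metadata = session_metadata(), labels = NULL) {
  if (!is.character(session_id) || length(session_id) != 1L)
    stop("`session_id` must be a single string")
  if (!is.character(therapist_id) || length(therapist_id) != 1L)
    stop("`therapist_id` must be a single string")
  if (!is.list(utterances) || !all(vapply(utterances, inherits, TRUE, "ctrs_utterance")))
    stop("`utterances` must be a list of ctrs_utterance objects")
  if (length(utterances) > 1L) {
    starts <- vapply(utterances, `[[`, 0, "start_s")
    if (is.unsorted(starts)) stop("utterances must be sorted by start_s")
  }
  if (!inherits(metadata, "ctrs_metadata")) stop("`metadata` must be ctrs_metadata")
  if (!is.null(labels) && !inherits(labels, "ctrs_scores"))
    stop("`labels` must be ctrs_scores or NULL")
  structure(list(session_id = session_id, therapist_id = therapist_id,
                 utterances = utterances, metadata = metadata, labels = labels),
            class = "ctrs_session")
}

#' @export
print.ctrs_session <- function(x, ...) {
  roles <- vapply(x$utterances, `[[`, "", "role")
  cat("<ctrs_session> ", x$session_id, " (therapist ", x$therapist_id, ")\n",
      "  ", length(x$utterances), " utterances (",
      sum(roles == "therapist"), " therapist / ", sum(roles == "patient"),
      " patient)\n", sep = "")
  if (!is.null(x$labels))
    cat("  total CTRS ", x$labels$total, " -> ",
        binarize_total(x$labels$total), "\n", sep = "")
  else cat("  unlabeled\n")
  invisible(x)
}

#' Read a corpus of coded session transcripts from JSONL
#'
#' One session per line:
#' `{"session_id", "therapist_id", "metadata": {...}, "utterances": [...],
#' "ctrs": {...} | null}`. A line whose `ctrs` object does not cover all 11
#' codes yields an *unlabeled* session (labels dropped, filtering left to the
#' caller).
#'
#' @param path Path to a JSONL transcript file.
#' @return List of [session_transcript()] objects, input order preserved.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sessions <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error on line ", i, ": ", conditionMessage(e)))
    sessions[[i]] <- tryCatch(session_from_record(rec),
                              error = function(e)
                                stop("invalid record on line ", i, ": ",
                                     conditionMessage(e)))
    ids[[i]] <- sessions[[i]]$session_id
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate session_id in corpus: ", paste(unique(dup), collapse = ", "))
  sessions
}

session_from_record <- function(rec) {
  md <- rec$metadata
  meta <- session_metadata(
    clinic = md$clinic %||% "unknown",
    level_of_care = md$level_of_care %||% "unknown",
    population = md$population %||% "unknown",
    assessment_time = md$assessment_time %||% "unknown")
  utts <- lapply(rec$utterances, function(u)
    utterance(u$role, u$text, u$start_s, u$end_s))
  labels <- NULL
  if (!is.null(rec$ctrs)) {
    codes <- unlist(rec$ctrs)
    # partial code sets load as unlabeled; downstream training rejects them
    if (all(CTRS_CODES %in% names(codes)) && !any(is.na(codes[CTRS_CODES])))
      labels <- ctrs_scores(codes[CTRS_CODES])
  }
  session_transcript(rec$session_id, rec$therapist_id, utts, meta, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus of session transcripts to JSONL
#'
#' Inverse of [read_corpus()]: the round trip reproduces every record
#' field-for-field.
#'
#' @param sessions List of [session_transcript()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(sessions, path) {
  lines <- vapply(sessions, function(s) {
    utts <- lapply(s$utterances, function(u)
      list(role = u$role, text = u$text, start_s = u$start_s, end_s = u$end_s))
    rec <- list(session_id = s$session_id, therapist_id = s$therapist_id,
                metadata = unclass(s$metadata), utterances = utts,
                ctrs = if (is.null(s$labels)) NULL else as.list(s$labels$codes))
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export session labels as CSV
#'
#' @param sessions List of sessions; unlabeled ones are skipped.
#' @param path Output CSV path (session_id, 11 code columns, total).
#' @return The data frame written, invisibly.
#' @export
write_labels_csv <- function(sessions, path) {
  lab <- Filter(function(s) !is.null(s$labels), sessions)
  df <- data.frame(session_id = vapply(lab, `[[`, "", "session_id"),
                   stringsAsFactors = FALSE)
  for (code in CTRS_CODES)
    df[[code]] <- vapply(lab, function(s) s$labels$codes[[code]], 0L)
  df$total <- vapply(lab, function(s) s$labels$total, 0L)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Merge adjacent same-role talk turns separated by short silences
#'
#' Consecutive utterances with the same speaker role whose silence gap is
#' strictly shorter than `max_gap` seconds are merged (texts joined with a
#' single space, time span extended), applied transitively left to right.
#' A gap exactly equal to `max_gap` does **not** merge.
#'
#' @param utterances List of [utterance()] objects sorted by start time.
#' @param max_gap Merge threshold in seconds (default 2).
#' @return List of merged utterances; never more than the input count.
#' @export
merge_turns <- function(utterances, max_gap = 2.0) {
  if (length(utterances) <= 1L) return(utterances)
  starts <- vapply(utterances, `[[`, 0, "start_s")
  if (is.unsorted(starts)) stop("utterances must be sorted by start_s")
  out <- list(utterances[[1L]])
  for (u in utterances[-1L]) {
    prev <- out[[length(out)]]
    if (u$role == prev$role && (u$start_s - prev$end_s) < max_gap) {
      prev$text <- if (nzchar(prev$text) && nzchar(u$text))
        paste(prev$text, u$text) else paste0(prev$text, u$text)
      prev$end_s <- max(prev$end_s, u$end_s)
      out[[length(out)]] <- prev
    } else {
      out[[length(out) + 1L]] <- u
    }
  }
  out
}

#' Keep only utterances of one speaker role
#'
#' @param session A [session_transcript()].
#' @param role `"therapist"` or `"patient"`.
#' @return The session with only matching utterances (order preserved);
#'   metadata and labels untouched. An empty utterance list is valid.
#' @export
filter_role <- function(session, role = c("therapist", "patient")) {
  role <- match.arg(role)
  keep <- vapply(session$utterances, function(u) u$role == role, TRUE)
  session$utterances <- session$utterances[keep]
  session
}

#' Build per-field metadata vocabularies from training sessions
#'
#' @param sessions List of sessions (training folds only, to avoid leakage).
#' @return Named list of sorted category vectors, one per metadata field.
#' @export
build_metadata_vocab <- function(sessions) {
  vocab <- lapply(METADATA_FIELDS, function(f)
    sort(unique(vapply(sessions, function(s) s$metadata[[f]], ""))))
  names(vocab) <- METADATA_FIELDS
  vocab
}

#' One-hot encode session metadata
#'
#' Each field becomes a block of `length(categories) + 1` indicator slots; the
#' extra slot is reserved for categories unseen in the vocabulary, so encoding
#' never fails and train/test dimensions always agree. Exactly one slot per
#' block is active.
#'
#' @param metadata A [session_metadata()] object.
#' @param vocab Per-field category lists from [build_metadata_vocab()].
#' @return Numeric 0/1 vector of length `sum(lengths(vocab) + 1)`.
#' @export
encode_metadata <- function(metadata, vocab) {
  blocks <- lapply(METADATA_FIELDS, function(f) {
    cats <- vocab[[f]]
    block <- numeric(length(cats) + 1L)
    idx <- match(metadata[[f]], cats)
    block[if (is.na(idx)) length(block) else idx] <- 1
    block
  })
  unlist(blocks)
}

#' Binarize a total CTRS score into a competence label
#'
#' In clinical practice a total CTRS at or above 40 indicates competent
#' delivery of CBT.
#'
#' @param total Total CTRS score(s), each in `[0, 66]`.
#' @param threshold Competence threshold (default 40).
#' @return Factor with levels `low`, `high`; `high` iff `total >= threshold`.
#' @export
binarize_total <- function(total, threshold = 40L) {
  if (any(is.na(total)) || any(total < 0 | total > 66))
    stop("total CTRS must lie in [0, 66]")
  factor(ifelse(total >= threshold, "high", "low"), levels = c("low", "high"))
}
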