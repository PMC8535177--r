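#' Configuration for the synthetic coded-therapy corpus generator
#'
#' The generator emulates the statistical structure of real coded CBT corpora:
#' multi-turn therapist/patient dialogue (turns per session drawn around
#' 430 +/- 230, therapist talk-turn share near 47%), eleven 0-6 Likert codes
#' whose total binarizes at 40 into an unbalanced low/high split, therapists
#' with several sessions each, four categorical metadata variables correlated
#' with scores, and code-specific lexical marker tokens localized early
#' (agenda-like), early+late (homework-like) or uniformly (feedback-like) in
#' the session.
#'
#' The latent score model is additive Gaussian, then rounded and clamped to
#' `[0, 6]`: for session \eqn{s} of therapist \eqn{i} and code \eqn{c},
#' \deqn{y_{sc} = \mathrm{clamp}(\mathrm{round}(b + m_s + I_{sc} +
#'   \epsilon_{sc}), 0, 6), \quad I_{sc} = u_i + d_{sc},}
#' where \eqn{u_i} is the therapist skill offset (shared across that
#' therapist's sessions and codes), \eqn{d_{sc}} a per-session-and-code
#' deviation, \eqn{m_s} the summed metadata effect, and \eqn{\epsilon}
#' unexplained coder noise. Marker-token counts are proportional to the
#' intensity \eqn{I_{sc}}, so the transcript text carries the skill and
#' session components but not the metadata or noise components — which is
#' exactly the headroom that metadata fusion can close.
#'
#' @param n_therapists Number of therapists.
#' @param sessions_per_therapist Sessions per therapist.
#' @param turns_mean,turns_sd Normal draw for total talk turns per session,
#'   clamped to `[60, 900]`.
#' @param words_per_turn Mean filler tokens per turn (Poisson, min 3).
#' @param base Baseline latent level per code.
#' @param skill_sd SD of the therapist skill offset.
#' @param dev_sd SD of the per-session, per-code intensity deviation.
#' @param noise_sd SD of unexplained per-code coder noise.
#' @param metadata_effect Named per-variable effect amplitudes; each variable's
#'   categories get effects spread evenly over `[-amp, +amp]` per code.
#' @param effect_size Marker tokens planted per 100 therapist turns per unit
#'   of (shifted, floored) intensity.
#' @param localization Named character vector mapping each code to
#'   `"early"`, `"early_late"` or `"uniform"`.
#' @param early_frac Fraction of therapist turns counting as "early" (and,
#'   symmetrically, "late").
#' @param patient_signal If `TRUE`, plant half-strength markers into patient
#'   turns as well (for all-utterance configurations); by default patient
#'   turns carry only filler vocabulary.
#' @param asr_error_rate Per-token probability of substitution by a random
#'   filler token, simulating transcription errors.
#' @param seed Integer RNG seed; a fixed seed reproduces the corpus exactly.
#' @return An object of class `ctrs_simconfig`.
#' @export
simulation_config <- function(n_therapists = 60L,
                              sessions_per_therapist = 10L,
                              turns_mean = 430, turns_sd = 230,
                              words_per_turn = 10,
                              base = 3.25, skill_sd = 0.8, dev_sd = 1.0,
                              noise_sd = 0.25,
                              metadata_effect = c(clinic = 0.25,
                                                  level_of_care = 0.25,
                                                  population = 0.15,
                                                  assessment_time = 0.30),
                              effect_size = 3,
                              localization = default_localization(),
                              early_frac = 0.15,
                              patient_signal = FALSE,
                              asr_error_rate = 0,
                              seed = 20260101L) {
  stopifnot(n_therapists >= 1, sessions_per_therapist >= 1,
            turns_mean > 0, words_per_turn >= 1,
            all(localization %in% c("early", "early_late", "uniform")),
            all(CTRS_CODES %in% names(localization)),
            early_frac > 0, early_frac < 0.5,
            asr_error_rate >= 0, asr_error_rate < 1)
  structure(as.list(environment()), class = "ctrs_simconfig")
}

#' @rdname simulation_config
#' @export
default_localization <- function() {
  loc <- rep("uniform", length(CTRS_CODES))
  names(loc) <- CTRS_CODES
  loc["ag"] <- "early"       # agenda-setting opens the session
  loc["hw"] <- "early_late"  # homework is reviewed early and assigned late
  loc                        # feedback ("fb") and the rest stay uniform
}

#' Marker token for one CTRS code
#'
#' Invented non-word strings, so no filler token ever collides with a marker.
#' @param code Code abbreviation.
#' @return Single token string.
#' @export
marker_token <- function(code) paste0("zq", code, "ol")

SIM_FILLER <- sprintf("w%03d", 1:60)

sim_metadata_categories <- function(cfg) {
  list(
    clinic = sprintf("clinic%02d", 1:10),
    level_of_care = c("inpatient", "outpatient", "intensive_outpatient",
                      "residential", "school_based", "act"),
    population = c("child", "adolescent", "adult", "geriatric",
                   "substance_use", "smi", "lgbtqi", "forensic",
                   "homelessness"),
    assessment_time = c("pre_workshop", "post_workshop", "m3", "m6", "m9",
                        "m12", "m24"))
}

#' Generate a synthetic coded therapy corpus
#'
#' See [simulation_config()] for the generative model. Timestamps use
#' exponential inter-turn gaps and occasional consecutive same-role turns, so
#' [merge_turns()] is exercised on the output.
#'
#' @param config A [simulation_config()].
#' @return List with elements `sessions` (list of labeled
#'   [session_transcript()] objects) and `truth` (per-session ground truth:
#'   skill offsets, metadata contributions, latent intensities and scores, and
#'   the exact marker turn indices planted per code).
#' @export
generate_corpus <- function(config = simulation_config()) {
  stopifnot(inherits(config, "ctrs_simconfig"))
  set.seed(config$seed)
  cats <- sim_metadata_categories(config)
  # evenly spaced per-category effects, one ladder per metadata variable
  effects <- lapply(names(cats), function(v) {
    k <- length(cats[[v]])
    e <- seq(-1, 1, length.out = k) * config$metadata_effect[[v]]
    names(e) <- cats[[v]]
    e
  })
  names(effects) <- names(cats)

  n_sess <- config$n_therapists * config$sessions_per_therapist
  skills <- rnorm(config$n_therapists, 0, config$skill_sd)
  ther_ids <- sprintf("T%03d", seq_len(config$n_therapists))
  ther_clinic <- sample(cats$clinic, config$n_therapists, replace = TRUE)

  sessions <- vector("list", n_sess)
  truth <- vector("list", n_sess)
  si <- 0L
  for (ti in seq_len(config$n_therapists)) {
    for (k in seq_len(config$sessions_per_therapist)) {
      si <- si + 1L
      id <- sprintf("S%04d", si)
      md <- session_metadata(
        clinic = ther_clinic[[ti]],
        level_of_care = sample(cats$level_of_care, 1L),
        population = sample(cats$population, 1L),
        assessment_time = sample(cats$assessment_time, 1L))
      m_s <- sum(vapply(names(cats), function(v) effects[[v]][[md[[v]]]], 0))

      dev <- rnorm(11, 0, config$dev_sd)
      intensity <- skills[[ti]] + dev
      eps <- rnorm(11, 0, config$noise_sd)
      latent <- config$base + m_s + intensity + eps
      scores <- pmin(6L, pmax(0L, as.integer(round(latent))))
      names(scores) <- CTRS_CODES

      gen <- sim_one_session(config, intensity)
      sessions[[si]] <- session_transcript(
        id, ther_ids[[ti]], gen$utterances, md, ctrs_scores(scores))
      truth[[si]] <- list(session_id = id, therapist_id = ther_ids[[ti]],
                          skill = skills[[ti]], metadata_contrib = m_s,
                          intensity = intensity, latent = latent,
                          scores = scores,
                          marker_turns = gen$marker_turns,
                          marker_counts = vapply(gen$marker_turns, length, 0L))
    }
  }
  names(truth) <- vapply(sessions, `[[`, "", "session_id")
  list(sessions = sessions, truth = truth)
}

# one session's turn sequence plus planted markers; intensity is the 11-vector
sim_one_session <- function(config, intensity) {
  n_turns <- max(60L, min(900L, as.integer(round(
    rnorm(1, config$turns_mean, config$turns_sd)))))
  # role Markov chain: rare same-role repeats exercise turn merging;
  # asymmetric stay-probabilities put the therapist share just under half
  roles <- character(n_turns)
  roles[[1L]] <- sample(c("therapist", "patient"), 1L)
  stay <- c(therapist = 0.10, patient = 0.16)
  r <- runif(n_turns)
  for (t in 2:n_turns)
    roles[[t]] <- if (r[[t]] < stay[[roles[[t - 1L]]]]) roles[[t - 1L]] else
      setdiff(c("therapist", "patient"), roles[[t - 1L]])

  lens <- pmax(3L, rpois(n_turns, config$words_per_turn))
  toks <- sample(SIM_FILLER, sum(lens), replace = TRUE)
  texts <- vapply(split(toks, rep(seq_len(n_turns), lens)),
                  paste, "", collapse = " ")

  ther_idx <- which(roles == "therapist")
  pat_idx <- which(roles == "patient")
  marker_turns <- vector("list", 11L)
  names(marker_turns) <- CTRS_CODES
  for (ci in seq_along(CTRS_CODES)) {
    # markers are planted at a *rate* per therapist turn: competence shows in
    # how often skill-relevant language occurs, not in absolute counts, so
    # the lexical signal is invariant to session length
    count <- as.integer(round(config$effect_size * (length(ther_idx) / 100) *
                                max(0, intensity[[ci]] + 1.5)))
    pos <- draw_marker_positions(ther_idx, count,
                                 config$localization[[CTRS_CODES[[ci]]]],
                                 config$early_frac)
    if (config$patient_signal && length(pat_idx) >= 2L) {
      pos <- c(pos, draw_marker_positions(
        pat_idx, count %/% 2L, config$localization[[CTRS_CODES[[ci]]]],
        config$early_frac))
    }
    for (p in pos) texts[[p]] <- paste(texts[[p]],
                                       marker_token(CTRS_CODES[[ci]]))
    marker_turns[[ci]] <- sort(pos)
  }

  if (config$asr_error_rate > 0) {
    texts <- vapply(texts, function(tx) {
      tk <- strsplit(tx, " ", fixed = TRUE)[[1L]]
      hit <- runif(length(tk)) < config$asr_error_rate
      tk[hit] <- sample(SIM_FILLER, sum(hit), replace = TRUE)
      paste(tk, collapse = " ")
    }, "", USE.NAMES = FALSE)
  }

  durs <- 0.35 * (lens + 1)
  gaps <- stats::rexp(n_turns, rate = 1 / 1.2)
  starts <- cumsum(c(0, head(durs, -1) + gaps[-1L]))
  utts <- lapply(seq_len(n_turns), function(t)
    utterance(roles[[t]], texts[[t]], starts[[t]], starts[[t]] + durs[[t]]))
  list(utterances = utts, marker_turns = marker_turns)
}

# positions (turn indices) for `count` markers under a localization pattern
draw_marker_positions <- function(turn_idx, count, localization, early_frac) {
  n <- length(turn_idx)
  if (n == 0L || count == 0L) return(integer(0))
  n_edge <- max(1L, ceiling(early_frac * n))
  pool <- switch(localization,
    early = turn_idx[seq_len(n_edge)],
    early_late = c(turn_idx[seq_len(n_edge)],
                   turn_idx[seq.int(n - n_edge + 1L, n)]),
    uniform = turn_idx)
  pool[sample.int(length(pool), count, replace = TRUE)]
}

#' Split a corpus into therapist-disjoint partitions
#'
#' @param sessions List of sessions.
#' @param fractions Named numeric vector of partition fractions (sums to 1),
#'   e.g. `c(train = .8, val = .1, test = .1)`. Each partition receives at
#'   least one therapist.
#' @param seed Integer seed for the therapist shuffle.
#' @return Named list of session lists, therapist-disjoint.
#' @export
make_splits <- function(sessions, fractions = c(train = 0.8, val = 0.1,
                                                test = 0.1),
                        seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  ther <- vapply(sessions, `[[`, "", "therapist_id")
  ids <- unique(ther)
  if (length(ids) < length(fractions))
    stop("need at least ", length(fractions), " therapists for ",
         length(fractions), " partitions")
  set.seed(seed)
  ids <- sample(ids)
  n_per <- diff(round(cumsum(c(0, fractions)) * length(ids)))
  n_per <- pmax(n_per, 1L)
  while (sum(n_per) > length(ids)) n_per[[which.max(n_per)]] <-
    n_per[[which.max(n_per)]] - 1L
  n_per[[length(n_per)]] <- length(ids) - sum(head(n_per, -1))
  assign <- rep(names(fractions), n_per)
  out <- lapply(names(fractions), function(p)
    sessions[ther %in% ids[assign == p]])
  names(out) <- names(fractions)
  out
}

#' Generate a corpus whose consecutive utterances share topical codewords
#'
#' Each session is assigned one topic from a small pool; every utterance of
#' the session carries the topic's codeword plus filler drawn from that
#' topic's dedicated sub-vocabulary. Consecutive utterances therefore share
#' topical vocabulary, while a randomly drawn second segment almost always
#' comes from a different topic — the topical coherence that makes
#' next-utterance prediction informative on real dialogue, at a scale a
#' freshly initialized small encoder can learn. The per-topic filler
#' sub-vocabularies also make the masked-token objective genuinely
#' learnable (context predicts the masked token's topic sub-vocabulary), so
#' masked-token training builds the topic-clustered embeddings that
#' pair-order prediction then exploits.
#'
#' @param n_sessions Number of sessions.
#' @param n_utterances Utterances per session.
#' @param n_topics Size of the topic pool.
#' @param words_per_topic Dedicated filler tokens per topic.
#' @param n_filler Filler tokens per utterance.
#' @param seed RNG seed.
#' @return List of unlabeled [session_transcript()] objects.
#' @export
generate_adjacency_corpus <- function(n_sessions = 40L, n_utterances = 30L,
                                      n_topics = 12L,
                                      words_per_topic = 8L,
                                      n_filler = 4L, seed = 1L) {
  stopifnot(n_topics >= 2L, words_per_topic >= 1L)
  set.seed(seed)
  topics <- sprintf("tpq%02dxz", seq_len(n_topics))
  subvocab <- lapply(seq_len(n_topics), function(k)
    sprintf("w%02dt%02d", seq_len(words_per_topic), k))
  lapply(seq_len(n_sessions), function(s) {
    topic <- sample.int(n_topics, 1L)
    utts <- lapply(seq_len(n_utterances), function(i) {
      toks <- sample(c(topics[[topic]],
                       sample(subvocab[[topic]], n_filler, replace = TRUE)))
      t0 <- (i - 1L) * 5
      utterance(if (i %% 2L) "therapist" else "patient",
                paste(toks, collapse = " "), t0, t0 + 4)
    })
    session_transcript(sprintf("A%03d", s), sprintf("AT%02d", (s %% 8L) + 1L),
                       utts)
  })
}
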