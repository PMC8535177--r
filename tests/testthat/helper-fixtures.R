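# shared fixture builders; everything is generated in code, no stored data

utt <- function(role, text, start, end) utterance(role, text, start, end)

# a tiny labeled session with both roles
tiny_session <- function(id = "s1", therapist = "t1", scores = NULL) {
  if (is.null(scores)) {
    scores <- rep(3L, 11)
    names(scores) <- ctrs_code_names()
  }
  session_transcript(
    id, therapist,
    list(utt("therapist", "hello there", 0, 2),
         utt("patient", "hi doc", 2.5, 4),
         utt("therapist", "lets set an agenda", 4.5, 8),
         utt("therapist", "for today", 8.5, 10),
         utt("patient", "sure", 12, 13)),
    session_metadata(clinic = "c1", level_of_care = "outpatient",
                     population = "adult", assessment_time = "pre"),
    ctrs_scores(scores))
}

# a small labeled random corpus for model-level tests (fast to embed/train)
small_corpus <- function(n_therapists = 12, sessions_per_therapist = 3,
                         seed = 42) {
  generate_corpus(simulation_config(
    n_therapists = n_therapists,
    sessions_per_therapist = sessions_per_therapist,
    turns_mean = 70, turns_sd = 20, words_per_turn = 6,
    seed = seed))$sessions
}

# random embedded session, labels optional
random_embedded <- function(id, L, d, meta_dim = 3, therapist = paste0("t", id),
                            labeled = TRUE) {
  codes <- sample(0:6, 11, replace = TRUE)
  names(codes) <- ctrs_code_names()
  structure(list(session_id = as.character(id), therapist_id = therapist,
                 vectors = matrix(rnorm(L * d), L, d),
                 metadata_vec = rnorm(meta_dim),
                 labels = if (labeled) ctrs_scores(codes),
                 n_utterances = L),
            class = "ctrs_embedded")
}

tiny_model_config <- function(...) {
  model_config(recurrent_units = 4, attention_hidden = 3, mlp_hidden = 5,
               seq_cap = 16, batch_size = 4, max_epochs = 3, patience = 2,
               ...)
}

expect_close <- function(a, b, tol = 1e-6) expect_lt(max(abs(a - b)), tol)
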