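Package: ctrscore
Title: Session-Level Quality Scoring of Cognitive Behavioral Therapy Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated session-level behavioral coding of Cognitive Behavioral
    Therapy (CBT) transcripts on the Cognitive Therapy Rating Scale (CTRS).
    Provides a data model and JSONL I/O for coded, role-tagged session
    transcripts (talk-turn merging, role filtering, metadata one-hot encoding,
    total-score binarization); pluggable utterance embedding backends including
    a deterministic hash embedder and a small trainable transformer encoder
    with masked-token and next-utterance pretraining for in-domain adaptation;
    bidirectional GRU sequence encoders with per-code additive attention heads,
    trained either as a single-task binary competence classifier or as a
    multi-task regressor of the eleven CTRS codes whose sum is binarized at the
    clinical threshold of 40; a unigram tf-idf + F-test + linear SVM reference
    system; therapist-grouped cross-validation with macro-F1 scoring and paired
    bootstrap significance tests; time-normalized attention saliency curves;
    and a seeded synthetic-corpus generator emulating the statistical structure
    of coded therapy sessions so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    e1071,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
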