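test_that("JSONL corpus round-trips field-for-field", {
  s1 <- tiny_session("s1", "t1")
  s2 <- tiny_session("s2", "t2", scores = stats::setNames(
    c(6L, 0L, 3L, 2L, 5L, 1L, 4L, 3L, 2L, 6L, 0L), ctrs_code_names()))
  s3 <- tiny_session("s3", "t1")
  s3$labels <- NULL
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(list(s1, s2, s3), f)
  back <- read_corpus(f)
  expect_length(back, 3L)
  expect_identical(vapply(back, `[[`, "", "session_id"), c("s1", "s2", "s3"))
  expect_identical(back[[2L]]$labels$codes, s2$labels$codes)
  expect_identical(back[[2L]]$labels$total, s2$labels$total)
  expect_null(back[[3L]]$labels)
  expect_identical(back[[1L]]$metadata$population, "adult")
  expect_equal(back[[1L]]$utterances[[3L]]$start_s, 4.5)
  # second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("sessions with incomplete code sets load as unlabeled", {
  s <- tiny_session()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(list(s), f)
  rec <- jsonlite::fromJSON(readLines(f), simplifyVector = FALSE)
  rec$ctrs$hw <- NULL
  rec$ctrs$ag <- NULL
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), f)
  back <- read_corpus(f)
  expect_null(back[[1L]]$labels)
})

test_that("malformed lines and duplicate ids are rejected with context", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(list(tiny_session("a")), f)
  writeLines(c(readLines(f), "{not json"), f)
  expect_error(read_corpus(f), "line 2")
  write_corpus(list(tiny_session("a"), tiny_session("a", "t2")), f)
  expect_error(read_corpus(f), "duplicate")
})

test_that("turn merging obeys the strict 2-second gap rule", {
  # gap 1s, same role: merge
  m <- merge_turns(list(utt("therapist", "hi", 0, 5),
                        utt("therapist", "there", 6, 8)))
  expect_length(m, 1L)
  expect_identical(m[[1L]]$text, "hi there")
  expect_equal(c(m[[1L]]$start_s, m[[1L]]$end_s), c(0, 8))
  # gap 2.5s: no merge; gap exactly 2.0s: no merge (strict inequality)
  expect_length(merge_turns(list(utt("therapist", "a", 0, 5),
                                 utt("therapist", "b", 7.5, 9))), 2L)
  expect_length(merge_turns(list(utt("therapist", "a", 0, 5),
                                 utt("therapist", "b", 7, 9))), 2L)
  # role change blocks merging
  m3 <- merge_turns(list(utt("therapist", "a", 0, 1),
                         utt("patient", "b", 1.2, 2),
                         utt("therapist", "c", 2.1, 3)))
  expect_length(m3, 3L)
  # transitive left-to-right chain collapses
  chain <- merge_turns(list(utt("therapist", "a", 0, 1),
                            utt("therapist", "b", 1.5, 2.5),
                            utt("therapist", "c", 3.0, 4)))
  expect_length(chain, 1L)
  expect_identical(chain[[1L]]$text, "a b c")
  expect_error(merge_turns(list(utt("therapist", "a", 5, 6),
                                utt("therapist", "b", 0, 1))), "sorted")
})

test_that("merging is idempotent and conserves words and per-role span", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:25, 1)
    utts <- list(); cur <- 0
    for (i in seq_len(n)) {   # sequential, non-overlapping talk turns
      dur <- runif(1, 0.2, 2)
      utts[[i]] <- utt(sample(c("therapist", "patient"), 1),
                       paste(sample(letters, sample(1:5, 1), TRUE),
                             collapse = " "),
                       cur, cur + dur)
      cur <- cur + dur + runif(1, 0, 4)
    }
    m1 <- merge_turns(utts)
    m2 <- merge_turns(m1)
    expect_identical(m1, m2)
    expect_lte(length(m1), length(utts))
    word_count <- function(us, role) sum(vapply(us, function(u)
      if (u$role == role) length(strsplit(u$text, " ")[[1L]]) else 0L, 0L))
    span <- function(us, role) sum(vapply(us, function(u)
      if (u$role == role) u$end_s - u$start_s else 0, 0))
    for (role in c("therapist", "patient")) {
      expect_identical(word_count(m1, role), word_count(utts, role))
      expect_gte(span(m1, role), span(utts, role) - 1e-9)
    }
  }
})

test_that("role filtering keeps order, metadata and labels, and is idempotent", {
  s <- tiny_session()
  th <- filter_role(s, "therapist")
  expect_length(th$utterances, 3L)
  expect_identical(vapply(th$utterances, `[[`, "", "text")[1:2],
                   c("hello there", "lets set an agenda"))
  expect_identical(th$labels$total, s$labels$total)
  expect_identical(filter_role(th, "therapist"), th)
  # all-patient session gives a valid empty result
  pat <- filter_role(filter_role(s, "patient"), "therapist")
  expect_length(pat$utterances, 0L)
  expect_s3_class(pat, "ctrs_session")
})

test_that("metadata one-hot encoding has reserved unknown slots per field", {
  # the reference corpus dimensions: 25 clinics + 6 + 9 + 7 categories
  vocab <- list(clinic = sprintf("c%02d", 1:25),
                level_of_care = sprintf("l%d", 1:6),
                population = sprintf("p%d", 1:9),
                assessment_time = sprintf("a%d", 1:7))
  md <- session_metadata(clinic = "c03", level_of_care = "l2",
                         population = "p9", assessment_time = "somewhere-new")
  v <- encode_metadata(md, vocab)
  expect_length(v, 25 + 6 + 9 + 7 + 4)
  # exactly one active slot per field block
  blocks <- split(v, rep(1:4, c(26, 7, 10, 8)))
  expect_identical(vapply(blocks, sum, 0), c(`1` = 1, `2` = 1, `3` = 1, `4` = 1))
  expect_equal(v[3], 1)                    # known clinic in its own slot
  expect_equal(unname(blocks[[4]][8]), 1)  # unseen category -> unknown slot
  # property: one active slot per block for arbitrary inputs
  set.seed(1)
  for (i in 1:25) {
    md2 <- session_metadata(sample(c("c01", "zzz"), 1), sample(c("l1", "x"), 1),
                            sample(c("p1", "y"), 1), sample(c("a1", "w"), 1))
    b2 <- split(encode_metadata(md2, vocab), rep(1:4, c(26, 7, 10, 8)))
    expect_true(all(vapply(b2, sum, 0) == 1))
  }
})

test_that("total binarization threshold is >= 40 and monotone", {
  expect_identical(as.character(binarize_total(40L)), "high")
  expect_identical(as.character(binarize_total(39L)), "low")
  expect_identical(as.character(binarize_total(0L)), "low")
  expect_identical(as.character(binarize_total(66L)), "high")
  lab <- binarize_total(0:66)
  expect_true(!is.unsorted(as.integer(lab)))  # monotone nondecreasing
  expect_error(binarize_total(67), "0, 66")
  expect_error(binarize_total(-1), "0, 66")
})

test_that("scores validate the 0-6 range and recompute the total", {
  codes <- stats::setNames(rep(2L, 11), ctrs_code_names())
  expect_identical(ctrs_scores(codes)$total, 22L)
  codes["hw"] <- 7L
  expect_error(ctrs_scores(codes), "0, 6")
  expect_error(ctrs_scores(codes[-1L]), "missing")
})
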