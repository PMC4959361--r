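test_that("retention reproduces the worked replacement example", {
  out <- retain_feedback(
    prev_top = paste0("d", 1:10),
    selected = c("d2", "d4", "d5", "d9"),
    next_top = c("d2", "d13", "d11", "d7", "d14", "d1", "d10", "d3", "d5", "d12")
  )
  expect_identical(out, c("d2", "d13", "d11", "d7", "d14", "d1", "d10",
                          "d4", "d5", "d9"))
})

test_that("retention handles the no-op and full-replacement extremes", {
  top <- paste0("d", 1:5)
  expect_identical(retain_feedback(top, c("d1", "d3"), top), top)
  # every selected document vanished: the last |r| slots are replaced, in
  # previous-round rank order
  out <- retain_feedback(paste0("d", 1:4), c("d2", "d4"),
                         c("n1", "n2", "n3", "n4"))
  expect_identical(out, c("n1", "n2", "d2", "d4"))
  expect_error(retain_feedback(top, "d99", top), "previous top list")
  expect_error(retain_feedback(top, "d1", paste0("d", 1:4)), "same length")
})

test_that("retention matches a literal replacement-walk simulation", {
  set.seed(13)
  for (rep in 1:30) {
    prev <- sprintf("p%02d", sample(99, 10))
    sel <- sample(prev, sample(1:5, 1))
    n_survive <- sample(0:9, 1)
    nxt <- sample(c(sample(prev, n_survive), sprintf("n%02d", 1:(10 - n_survive))))
    got <- retain_feedback(prev, sel, nxt)
    expect_identical(got, oracle_retain(prev, sel, nxt))
    # every selection present; non-displaced documents keep relative order
    expect_true(all(sel %in% got))
    kept <- got[got %in% nxt]
    expect_identical(kept, nxt[nxt %in% kept])
  }
})

test_that("a session runs initial search, accepts feedback and retains selections", {
  gen <- generate_corpus(n_docs = 40, n_relevant = 4, vocab_size = 200,
                         sentences_per_doc = c(5, 15), seed = 5)
  session <- search_session(gen$corpus, gen$query, chi = 10, k = 20)
  expect_error(submit_feedback(session, "d001"), "run_initial")
  session <- run_initial(session)
  expect_error(run_initial(session), "already")
  top <- session_top(session)
  expect_length(top, 10L)
  # the anchor guarantee: at least one planted document in the initial window
  sel <- intersect(top, gen$relevant_doc_ids)
  expect_gte(length(sel), 1L)
  s2 <- submit_feedback(session, sel)
  expect_identical(s2$round, 1L)
  expect_true(all(sel %in% session_top(s2)))
  # selecting a document twice equals selecting it once
  s2_dup <- submit_feedback(session, rep(sel, 2))
  expect_identical(session_ranking(s2)$doc_id, session_ranking(s2_dup)$doc_id)
  # consecutive rounds with the same selection keep it in the window
  s3 <- submit_feedback(s2, sel)
  expect_true(all(sel %in% session_top(s3)))
  expect_error(submit_feedback(s2, "not-a-doc"), "outside the current top")
  expect_error(submit_feedback(s2, character(0)), "no feedback")
})

test_that("sessions are reproducible end to end", {
  run_once <- function() {
    gen <- generate_corpus(n_docs = 30, n_relevant = 3, vocab_size = 150,
                           sentences_per_doc = c(5, 12), seed = 9)
    session <- run_initial(search_session(gen$corpus, gen$query, chi = 8, k = 15))
    sel <- intersect(session_top(session), gen$relevant_doc_ids)
    session <- submit_feedback(session, sel)
    tidy(session)
  }
  expect_identical(run_once(), run_once())
})

test_that("session persistence round-trips query, parameters and history", {
  gen <- generate_corpus(n_docs = 25, n_relevant = 3, vocab_size = 120,
                         sentences_per_doc = c(4, 10), seed = 3)
  corpus_path <- withr::local_tempfile(fileext = ".txt")
  write_corpus(gen$corpus, corpus_path)
  session <- run_initial(search_session(gen$corpus, gen$query, chi = 5, k = 10))
  sel <- intersect(session_top(session), gen$relevant_doc_ids)
  if (length(sel) > 0) session <- submit_feedback(session, sel)
  session_path <- withr::local_tempfile(fileext = ".json")
  save_session(session, session_path, corpus_path)
  back <- load_session(session_path)
  expect_identical(as.character(back$query), as.character(session$query))
  expect_identical(back$chi, session$chi)
  expect_identical(back$round, session$round)
  expect_identical(length(back$history), length(session$history))
  expect_equal(as.data.frame(session_ranking(back)),
               as.data.frame(session_ranking(session)))
})
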