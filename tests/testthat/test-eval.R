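test_that("average precision handles perfect, single-hit and empty cases", {
  expect_equal(average_precision(paste0("d", 1:5), paste0("d", 1:3)), 1)
  expect_equal(average_precision(c("a", "b", "c", "d"), "d", cutoff = 10), 0.25)
  expect_equal(average_precision(paste0("d", 1:5), "d99"), 0)
  expect_error(average_precision(character(0), "d1"), "empty ranking")
  # cutoff truncates: a hit below the cutoff does not count
  expect_equal(average_precision(c("a", "b", "c"), "c", cutoff = 2), 0)
})

test_that("average precision equals exhaustive enumeration on all small rankings", {
  docs <- paste0("d", 1:7)
  relevant <- c("d2", "d5", "d7")
  perms <- NULL
  # all 5040 orderings of seven documents
  perm_rec <- function(prefix, rest) {
    if (length(rest) == 0) {
      perms[[length(perms) + 1L]] <<- prefix
    } else {
      for (i in seq_along(rest)) perm_rec(c(prefix, rest[i]), rest[-i])
    }
  }
  perm_rec(character(0), docs)
  for (p in perms[seq(1, length(perms), by = 7)]) {
    expect_equal(average_precision(p, relevant),
                 oracle_ap(p, relevant, length(p)), tolerance = 1e-12)
    expect_equal(average_precision(p, relevant, cutoff = 4),
                 oracle_ap(p, relevant, 4), tolerance = 1e-12)
  }
})

test_that("mean average precision averages per-topic scores", {
  perfect <- list(ranked = c("a", "b"), relevant = c("a", "b"))
  miss <- list(ranked = c("a", "b"), relevant = "z")
  expect_equal(mean_average_precision(list(perfect, miss)), 0.5)
  expect_equal(mean_average_precision(list(perfect, perfect)), 1)
  runs <- tibble::tibble(ranked = list(c("a", "b"), c("b", "a")),
                         relevant = list("a", "a"))
  expect_equal(mean_average_precision(runs), mean(c(1, 0.5)))
})

test_that("qrels files round-trip and map grades 0/1/2", {
  path <- withr::local_tempfile(fileext = ".qrels")
  writeLines(c("t1 0 doc1 0", "t1 0 doc2 1", "t1 0 doc3 2", "t2 0 doc1 2"), path)
  j <- read_judgments(path)
  expect_identical(as.character(j$grade), c("NOT", "POSSIBLY", "DEFINITELY",
                                            "DEFINITELY"))
  expect_setequal(relevant_docs(j, "t1"), c("doc2", "doc3"))
  expect_identical(relevant_docs(j, "t1", mode = "definitely-only"), "doc3")
  expect_identical(relevant_docs(j, "t3"), character(0))
  out <- withr::local_tempfile(fileext = ".qrels")
  write_judgments(j, out)
  expect_equal(as.data.frame(read_judgments(out)), as.data.frame(j))
  writeLines("t1 0 doc1 9", path)
  expect_error(read_judgments(path), "unknown grade")
})

test_that("the simulated user selects all relevant in the window and stops without any", {
  gen <- generate_corpus(n_docs = 50, n_relevant = 5, vocab_size = 250,
                         sentences_per_doc = c(5, 20), seed = 21)
  sim <- simulate_user(gen$corpus, gen$query, gen$relevant_doc_ids,
                       chi = 10, rounds = 3, k = 20)
  expect_true(sim$feedback_capable)
  expect_gte(nrow(sim$metrics), 2L)
  expect_true(all(sim$metrics$ap10 >= 0 & sim$metrics$ap10 <= 1))
  # a topic whose relevant documents do not exist is not feedback-capable
  sim_none <- simulate_user(gen$corpus, gen$query, "no-such-doc",
                            chi = 10, rounds = 3, k = 20)
  expect_false(sim_none$feedback_capable)
  expect_identical(nrow(sim_none$metrics), 1L)
  # top-10 selections are a subset of top-20 selections (prefix property)
  sel10 <- intersect(session_top(sim$session, 10), gen$relevant_doc_ids)
  sel20 <- intersect(session_top(sim$session, 20), gen$relevant_doc_ids)
  expect_true(all(sel10 %in% sel20))
})

test_that("metrics report appends one MAP summary row per round", {
  gen <- generate_corpus(n_docs = 30, n_relevant = 3, vocab_size = 150,
                         sentences_per_doc = c(4, 12), seed = 33)
  sims <- list(
    simulate_user(gen$corpus, gen$query, gen$relevant_doc_ids,
                  topic_id = "t1", rounds = 2, k = 10),
    simulate_user(gen$corpus, gen$query, gen$relevant_doc_ids,
                  topic_id = "t2", rounds = 2, k = 10)
  )
  report <- metrics_report(sims)
  map_rows <- report[report$topic_id == "MAP", ]
  expect_gte(nrow(map_rows), 1L)
  r0 <- report[report$topic_id != "MAP" & report$round == 0, ]
  expect_equal(map_rows$ap10[map_rows$round == 0], mean(r0$ap10))
})
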