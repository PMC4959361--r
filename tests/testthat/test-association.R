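# The five-sentence worked example: Q = {3,2,6}, six unique concepts, N = 5.

test_that("per-sentence counts reproduce the worked example", {
  doc <- example_doc()
  q <- example_query()
  s <- doc$sentences
  expect_equal(partial_count_query(s[[1]], q), 1 / 3)
  expect_equal(partial_count_query(s[[5]], q), 2 / 3)
  expect_equal(partial_count_query(c("3", "2", "6", "9"), q), 1)
  expect_identical(binary_count_concept(s[[1]], "1"), 1L)
  expect_identical(binary_count_concept(s[[5]], "1"), 0L)
  expect_identical(binary_count_concept(character(0), "1"), 0L)
  expect_equal(joint_partial_count(s[[1]], q, "1"), 1 / 3)
  expect_equal(joint_partial_count(s[[3]], q, "1"), 2 / 3)
  expect_equal(joint_partial_count(s[[5]], q, "1"), 0)
})

test_that("pooled frequencies and weighted interest reproduce the worked example", {
  doc <- example_doc()
  q <- example_query()
  expect_equal(weighted_frequency_query(doc, q), 5 / 3)
  expect_identical(frequency_concept(doc, "1"), 4L)
  expect_equal(weighted_joint_frequency(doc, q, "1"), 1)
  expect_equal(weighted_interest(doc, q, "1"), 0.75)
  expect_error(weighted_interest(doc, q, "99"), "not in feedback")
  # query disjoint from every sentence: interest defined as 0
  expect_equal(weighted_interest(doc, c("77", "88"), "1"), 0)
})

test_that("mining forms one rule per unique concept, matching per-concept calls", {
  doc <- example_doc()
  q <- example_query()
  rules <- mine_associations(doc, q)
  expect_identical(nrow(rules), 6L)
  for (i in seq_len(nrow(rules))) {
    expect_equal(rules$interest_w[i], weighted_interest(doc, q, rules$concept[i]),
                 tolerance = 1e-12)
  }
  # ordering: ties at interest 2 broken by higher joint frequency, then ties
  # at 0.75 by ascending token
  expect_identical(rules$concept, c("6", "2", "3", "5", "1", "4"))
})

test_that("mining matches the brute-force oracle on random feedback sets", {
  set.seed(101)
  for (rep in 1:40) {
    sents <- random_sentences(allow_empty = TRUE)
    if (length(unlist(sents)) == 0) next
    q <- sample(as.character(1:40), sample(1:4, 1))
    z <- feedback_set(
      concept_corpus(list(concept_document("z", sents))), "z"
    )
    got <- mine_associations(z, q)
    want <- oracle_mine(sents, q)
    got <- got[order(got$concept), ]
    expect_equal(got$concept, want$concept)
    expect_equal(got$f_c, as.integer(want$f_c))
    expect_equal(got$f_joint_w, want$f_joint_w, tolerance = 1e-12)
    expect_equal(got$interest_w, want$interest_w, tolerance = 1e-12)
    # rule-frequency bounds
    expect_true(all(got$f_joint_w <= got$f_q_w + 1e-12))
    expect_true(all(got$f_joint_w <= got$f_c + 1e-12))
    expect_true(all(got$f_joint_w >= 0))
  }
})

test_that("weighted interest is invariant under duplicating the feedback set", {
  set.seed(202)
  for (rep in 1:10) {
    sents <- random_sentences(n_max = 20)
    q <- sample(as.character(1:40), 2)
    doc1 <- concept_document("a", sents)
    doc2 <- concept_document("b", c(sents, sents))
    r1 <- mine_associations(doc1, q)
    r2 <- mine_associations(doc2, q)
    expect_equal(r1$interest_w, r2$interest_w[match(r1$concept, r2$concept)],
                 tolerance = 1e-12)
  }
})

test_that("with a single-concept query the measure reduces to classic lift", {
  set.seed(303)
  sents <- random_sentences(n_max = 30)
  q <- unlist(sents)[1]
  n <- length(sents)
  for (concept in unique(unlist(sents))) {
    f_x <- sum(vapply(sents, function(s) q %in% s, logical(1)))
    f_y <- sum(vapply(sents, function(s) concept %in% s, logical(1)))
    f_xy <- sum(vapply(sents, function(s) q %in% s && concept %in% s, logical(1)))
    lift <- if (f_x == 0) 0 else n * f_xy / (f_x * f_y)
    expect_equal(weighted_interest(concept_document("z", sents), q, concept),
                 lift, tolerance = 1e-12)
  }
})

test_that("k-profiles rank, truncate and tie-break deterministically", {
  doc <- example_doc()
  q <- example_query()
  full <- build_k_profile(doc, q, k = 10)
  expect_identical(profile_concepts(full), c("6", "2", "3", "5", "1", "4"))
  expect_identical(attr(full, "n_transactions"), 5L)
  top1 <- build_k_profile(doc, q, k = 1)
  expect_identical(profile_concepts(top1), "6")
  # truncation below the unique-concept count
  small_doc <- concept_document("s", list(c("A", "B"), c("B", "C")))
  expect_identical(nrow(build_k_profile(small_doc, "B", k = 30)), 3L)
  # concept-free input profiles to nothing
  empty <- build_k_profile(concept_document("e", list(character(0))), "Q1", k = 5)
  expect_identical(nrow(empty), 0L)
})

test_that("feedback pooling keeps document order and collapses duplicates", {
  corp <- concept_corpus(list(
    concept_document("d1", list(c("A"), c("B"))),
    concept_document("d2", list(c("C")))
  ))
  z <- feedback_set(corp, c("d2", "d1", "d2"))
  expect_identical(z$n_transactions, 3L)
  expect_identical(unlist(z$sentences), c("C", "A", "B"))
  expect_error(feedback_set(corp, character(0)), "no feedback")
})

test_that("profile JSON serialization carries query, k and scores", {
  profile <- build_k_profile(example_doc(), example_query(), k = 3)
  js <- jsonlite::fromJSON(write_profile_json(profile), simplifyVector = FALSE)
  expect_identical(unlist(js$query), c("3", "2", "6"))
  expect_identical(js$k, 3L)
  expect_identical(vapply(js$concepts, function(x) x$concept, ""), c("6", "2", "3"))
})
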