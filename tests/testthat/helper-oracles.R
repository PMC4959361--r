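# Independent brute-force oracles and shared fixtures. The oracles are plain
# transliterations of the definitions, written with explicit loops and kept
# separate from the package's vectorised code paths.

# five-sentence worked-example document
example_doc <- function() {
  concept_document("ex1", list(
    c("1", "3", "4", "3", "5"),
    c("4", "5", "5", "1"),
    c("3", "5", "1", "3", "1", "6"),
    c("1", "5", "4", "4", "1"),
    c("5", "2", "4", "6", "2")
  ))
}

example_query <- function() concept_query(c("3", "2", "6"))

metamap_fixture_lines <- function() {
  readLines(system.file("extdata", "metamap_synthetic.txt",
                        package = "conceptrf"))
}

# random feedback set over an integer-token vocabulary
random_sentences <- function(n_max = 50, vocab_max = 40, allow_empty = FALSE) {
  vocab <- as.character(seq_len(sample(5:vocab_max, 1)))
  n <- sample(1:n_max, 1)
  lapply(seq_len(n), function(i) {
    len <- sample((if (allow_empty) 0 else 1):8, 1)
    if (len == 0) character(0) else sample(vocab, len, replace = TRUE)
  })
}

random_doc <- function(id, vocab, n_sent = sample(2:8, 1)) {
  concept_document(id, lapply(seq_len(n_sent), function(i) {
    sample(vocab, sample(2:10, 1), replace = TRUE)
  }))
}

random_corpus <- function(n_docs, vocab_max = 40) {
  vocab <- as.character(seq_len(vocab_max))
  concept_corpus(lapply(seq_len(n_docs), function(i) {
    random_doc(sprintf("d%03d", i), vocab)
  }))
}

# ---- association-mining oracle: explicit loops over the count definitions ----
oracle_mine <- function(sentences, query) {
  query <- unique(as.character(query))
  n <- length(sentences)
  concepts <- sort(unique(unlist(sentences)))
  cnt_q <- numeric(n)
  for (i in seq_len(n)) {
    hits <- 0
    for (q in query) if (q %in% sentences[[i]]) hits <- hits + 1
    cnt_q[i] <- hits / length(query)
  }
  f_q_w <- sum(cnt_q)
  out <- data.frame(concept = concepts, f_c = NA_real_, f_joint_w = NA_real_,
                    interest_w = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(concepts)) {
    f_c <- 0
    f_joint <- 0
    for (i in seq_len(n)) {
      present <- concepts[j] %in% sentences[[i]]
      if (present) {
        f_c <- f_c + 1
        f_joint <- f_joint + cnt_q[i] * 1
      }
    }
    out$f_c[j] <- f_c
    out$f_joint_w[j] <- f_joint
    out$interest_w[j] <- if (f_q_w == 0) 0 else n * f_joint / (f_q_w * f_c)
  }
  out
}

# ---- accumulative TF-IDF oracle: double loop, log base 10 ----
oracle_atfidf <- function(corpus, query) {
  query <- unique(as.character(query))
  m <- nrow(corpus)
  token_lists <- lapply(corpus$sentences, function(s) unlist(s))
  scores <- numeric(m)
  for (i in seq_len(m)) {
    toks <- token_lists[[i]]
    if (length(toks) == 0) next
    acc <- 0
    for (q in query) {
      df <- 0
      for (jj in seq_len(m)) if (q %in% token_lists[[jj]]) df <- df + 1
      if (df == 0) next
      acc <- acc + (sum(toks == q) / length(toks)) * log10(m / df)
    }
    scores[i] <- acc
  }
  data.frame(doc_id = corpus$doc_id, score = scores, stringsAsFactors = FALSE)
}

# ---- truncated RBO oracle: literal prefix loop ----
oracle_rbo <- function(a, b, phi, k) {
  total <- 0
  for (d in seq_len(k)) {
    pa <- a[seq_len(min(d, length(a)))]
    pb <- b[seq_len(min(d, length(b)))]
    total <- total + phi^(d - 1) * length(intersect(pa, pb)) / d
  }
  (1 - phi) * total
}

# ---- average-precision oracle: explicit rank walk ----
oracle_ap <- function(ids, relevant, cutoff) {
  ids <- head(ids, cutoff)
  precs <- c()
  found <- 0
  for (r in seq_along(ids)) {
    if (ids[r] %in% relevant) {
      found <- found + 1
      precs <- c(precs, found / r)
    }
  }
  if (found == 0) 0 else sum(precs) / found
}

# ---- retention oracle: literal replacement walk on a mutable copy ----
oracle_retain <- function(prev_top, selected, next_top) {
  selected <- selected[order(match(selected, prev_top))]
  xi <- setdiff(selected, next_top)
  out <- next_top
  pos <- length(out)
  while (length(xi) > 0 && pos >= 1) {
    if (!(out[pos] %in% selected)) {
      out[pos] <- xi[length(xi)]
      xi <- xi[-length(xi)]
    }
    pos <- pos - 1
  }
  stopifnot(length(xi) == 0)
  out
}

# deterministic expected ranking: sort an (doc_id, score) frame the way the
# package's tie-break is specified
oracle_sort <- function(scores) {
  scores[order(-scores$score, scores$doc_id), "doc_id"]
}
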