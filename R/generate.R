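#' Generate a synthetic concept corpus with planted relevant documents
#'
#' Emulates a concept-annotated literature collection for offline testing of
#' the full feedback pipeline. Background documents draw concepts from a
#' Zipf-like frequency distribution over the vocabulary. Relevant documents
#' additionally contain "signal sentences" in which one or more query
#' concepts co-occur with concepts from a designated signal set; the
#' co-occurrence rate is the per-sentence probability of planting such a
#' sentence. The first relevant document is an anchor with a boosted planting
#' rate and the full query in every signal sentence, so at least one relevant
#' document reaches the top of the initial TF-IDF ranking and feedback is
#' possible. With `co_occurrence_rate = 0` nothing is planted and the
#' "relevant" documents are indistinguishable from background (a negative
#' control).
#'
#' Query concepts are drawn from moderately common vocabulary ranks (top
#' 2--12%), so background documents contain them by chance; signal concepts
#' come from rarer ranks (12--40%). A fraction `decoy_rate` of the
#' non-relevant documents are keyword decoys: they plant query concepts at
#' the same per-sentence rate as the relevant documents but carry no signal
#' concepts, emulating the keyword-matching but off-topic hits that make
#' purely term-based initial rankings noisy. Decoys score like relevant
#' documents under TF-IDF yet share no signal concepts with the feedback
#' profile, which is exactly the situation relevance feedback exists to fix.
#'
#' All randomness is governed by the single `seed`; the caller's RNG state is
#' saved and restored, so the generator leaves no global side effects.
#'
#' @param n_docs Number of documents.
#' @param n_relevant Number of planted relevant documents (<= `n_docs`).
#' @param vocab_size Vocabulary size.
#' @param sentences_per_doc Length-2 integer range of sentences per document.
#' @param tokens_per_sentence Length-2 integer range of tokens per sentence.
#' @param query_size Number of query concepts.
#' @param signal_concepts Optional explicit signal-concept tokens; when
#'   `NULL`, `n_signal` concepts are drawn from the signal pool.
#' @param n_signal Number of signal concepts to draw.
#' @param co_occurrence_rate Per-sentence probability, in a relevant
#'   document, of a planted query/signal co-occurrence sentence. Decoys plant
#'   query-only sentences at the same rate.
#' @param decoy_rate Fraction of non-relevant documents that are keyword
#'   decoys.
#' @param zipf_exponent Exponent of the Zipf-like background frequencies.
#' @param seed Integer seed controlling all randomness.
#' @param topic_id Topic label used in the bundled judgments.
#' @return A list with elements `corpus` ([concept_corpus()]), `query`
#'   ([concept_query()]), `relevant_doc_ids`, `signal_concepts` and
#'   `judgments` (a `relevance_judgments` tibble grading the planted
#'   documents DEFINITELY).
#' @examples
#' gen <- generate_corpus(n_docs = 20, n_relevant = 3, vocab_size = 100,
#'                        seed = 1)
#' rank_initial(gen$corpus, gen$query)
#' @export
generate_corpus <- function(n_docs = 100L,
                            n_relevant = 8L,
                            vocab_size = 500L,
                            sentences_per_doc = c(5L, 50L),
                            tokens_per_sentence = c(2L, 20L),
                            query_size = 3L,
                            signal_concepts = NULL,
                            n_signal = 5L,
                            co_occurrence_rate = 0.6,
                            decoy_rate = 0.2,
                            zipf_exponent = 1.07,
                            seed = 1L,
                            topic_id = "topic1") {
  stopifnot(n_docs >= 1, n_relevant >= 0, n_relevant <= n_docs,
            length(sentences_per_doc) == 2L, length(tokens_per_sentence) == 2L,
            sentences_per_doc[1] >= 1, tokens_per_sentence[1] >= 1,
            sentences_per_doc[1] <= sentences_per_doc[2],
            tokens_per_sentence[1] <= tokens_per_sentence[2],
            co_occurrence_rate >= 0, co_occurrence_rate <= 1,
            decoy_rate >= 0, decoy_rate <= 1,
            query_size >= 1)
  if (query_size > vocab_size) {
    abort("infeasible generator settings: query_size exceeds vocab_size")
  }

  vocab <- sprintf("C%04d", seq_len(vocab_size))
  zipf_w <- 1 / seq_len(vocab_size)^zipf_exponent

  # query from moderately common ranks, signal from rarer ranks
  q_lo <- max(2L, min(11L, vocab_size - query_size + 1L))
  q_hi <- min(vocab_size, max(q_lo + query_size - 1L, round(vocab_size * 0.12)))
  s_lo <- q_hi + 1L
  n_sig <- if (is.null(signal_concepts)) n_signal else 0L
  s_hi <- min(vocab_size, max(s_lo + n_sig - 1L, round(vocab_size * 0.4)))
  if (is.null(signal_concepts) && (s_lo > vocab_size || s_hi - s_lo + 1L < n_sig)) {
    abort("infeasible generator settings: vocabulary too small for query and signal pools")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  query <- concept_query(sample(vocab[q_lo:q_hi], query_size))
  if (is.null(signal_concepts)) {
    signal_concepts <- sample(setdiff(vocab[s_lo:s_hi], query), n_signal)
  } else {
    signal_concepts <- as.character(signal_concepts)
    check_tokens(signal_concepts, "signal_concepts")
  }

  id_width <- max(3L, nchar(n_docs))
  doc_ids <- sprintf(paste0("d%0", id_width, "d"), seq_len(n_docs))
  relevant_idx <- if (n_relevant > 0) sort(sample(n_docs, n_relevant)) else integer(0)
  anchor_idx <- if (n_relevant > 0) relevant_idx[1] else NA_integer_
  other_idx <- setdiff(seq_len(n_docs), relevant_idx)
  n_decoy <- round(decoy_rate * length(other_idx))
  decoy_idx <- if (n_decoy > 0) sort(sample(other_idx, n_decoy)) else integer(0)

  lens_for <- function(n) {
    sample(seq(tokens_per_sentence[1], tokens_per_sentence[2]), n, replace = TRUE)
  }

  docs <- lapply(seq_len(n_docs), function(i) {
    # topical coherence: each document writes from its own concept pool, so
    # concepts recur within a document as they do in real articles
    breadth <- min(vocab_size, max(20L, round(vocab_size * 0.08)))
    doc_vocab_idx <- sample(vocab_size, breadth, prob = zipf_w)
    background_sentence <- function(len) {
      sample(vocab[doc_vocab_idx], len, replace = TRUE,
             prob = zipf_w[doc_vocab_idx])
    }
    n_sent <- sample(seq(sentences_per_doc[1], sentences_per_doc[2]), 1L)
    lens <- lens_for(n_sent)
    sents <- lapply(lens, background_sentence)
    role <- if (i %in% relevant_idx) "relevant" else
      if (i %in% decoy_idx) "decoy" else "background"
    if (role != "background" && co_occurrence_rate > 0) {
      is_anchor <- identical(i, anchor_idx)
      rate <- if (is_anchor) max(co_occurrence_rate, 0.7) else co_occurrence_rate
      planted <- which(stats::runif(n_sent) < rate)
      if (is_anchor && length(planted) == 0L) {
        planted <- 1L
      }
      for (p in planted) {
        q_part <- if (is_anchor) {
          as.character(query)
        } else {
          sample(query, sample(length(query), 1L))
        }
        s_part <- if (role == "relevant") {
          sample(signal_concepts,
                 sample(min(3L, length(signal_concepts)), 1L))
        } else {
          character(0)
        }
        seed_toks <- c(q_part, s_part)
        fill <- max(0L, lens[p] - length(seed_toks))
        sents[[p]] <- sample(c(seed_toks, background_sentence(fill)))
      }
    }
    concept_document(doc_ids[[i]], sents)
  })

  relevant_ids <- doc_ids[relevant_idx]
  judgments <- new_judgments(tibble(
    topic_id = rep(topic_id, length(relevant_ids)),
    doc_id = relevant_ids,
    grade = factor(rep("DEFINITELY", length(relevant_ids)),
                   levels = grade_levels)
  ))
  list(corpus = concept_corpus(docs),
       query = query,
       relevant_doc_ids = relevant_ids,
       signal_concepts = signal_concepts,
       judgments = judgments)
}
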