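#' Term frequency of a concept in a document
#'
#' Frequency of the concept among the document's flattened tokens divided by
#' the total token count (multiplicity counted, not unique concepts).
#'
#' @param doc A [concept_document()].
#' @param concept Single concept token.
#' @return A value in \[0, 1\].
#' @export
term_frequency <- function(doc, concept) {
  stopifnot(inherits(doc, "concept_document"), length(concept) == 1L)
  tokens <- doc_tokens(doc)
  if (length(tokens) == 0L) {
    abort(sprintf("no concepts in document '%s'", doc$doc_id))
  }
  sum(tokens == concept) / length(tokens)
}

#' Inverse document frequency of a concept
#'
#' `log10(|D| / DF_c)` where `DF_c` is the number of documents containing the
#' concept. A concept absent from the corpus has IDF 0 by convention: it
#' cannot discriminate documents it never appears in. Base 10 is used; the
#' ranking is invariant to the base, which only fixes reported score values.
#'
#' @param corpus A `concept_corpus`.
#' @param concept Single concept token.
#' @return Non-negative real.
#' @export
inverse_document_frequency <- function(corpus, concept) {
  stopifnot(inherits(corpus, "concept_corpus"), length(concept) == 1L)
  idx <- df_index(corpus)
  df <- idx$df[match(concept, idx$concept)]
  if (is.na(df) || df == 0L) {
    return(0)
  }
  log10(nrow(corpus) / df)
}

# Accumulative TF-IDF of every document for a query, vectorised over the
# corpus. Returns a tibble (doc_id, score) in corpus order.
atfidf_scores <- function(corpus, query) {
  query <- as_query(query)
  idx <- df_index(corpus)
  df <- idx$df[match(query, idx$concept)]
  idf <- ifelse(is.na(df) | df == 0L, 0, log10(nrow(corpus) / df))
  scores <- vapply(corpus$sentences, function(sents) {
    tokens <- unlist(sents, use.names = FALSE)
    if (length(tokens) == 0L) {
      return(0)
    }
    counts <- vapply(query, function(q) sum(tokens == q), numeric(1))
    sum(counts / length(tokens) * idf)
  }, numeric(1))
  tibble(doc_id = corpus$doc_id, score = scores)
}

#' Accumulative TF-IDF of a document for a query
#'
#' The query's score for a document is the sum of the TF-IDF weights of each
#' query concept in that document. Documents with no tokens score 0.
#'
#' @param corpus A `concept_corpus`.
#' @param query A [concept_query()] or character vector (deduplicated).
#' @param doc A `concept_document` or a doc_id present in `corpus`.
#' @return Non-negative real.
#' @examples
#' corp <- concept_corpus(list(
#'   concept_document("d1", list(c("C1", "C2"))),
#'   concept_document("d2", list(c("C3")))
#' ))
#' a_tf_idf(corp, concept_query("C1"), "d1")
#' @export
a_tf_idf <- function(corpus, query, doc) {
  query <- as_query(query)
  if (is.character(doc)) {
    doc <- corpus_doc(corpus, doc)
  }
  stopifnot(inherits(doc, "concept_document"))
  tokens <- doc_tokens(doc)
  if (length(tokens) == 0L) {
    return(0)
  }
  sum(vapply(query, function(q) {
    term_frequency(doc, q) * inverse_document_frequency(corpus, q)
  }, numeric(1)))
}

# descending score, ascending doc_id; determinism the whole pipeline relies on
rank_entries <- function(scores) {
  scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$doc_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

new_ranked_list <- function(entries, scoring) {
  entries <- as_tibble(entries)[c("doc_id", "score", "rank")]
  structure(entries,
            scoring = scoring,
            class = c("ranked_list", class(entries)))
}

#' Initial ranking of a corpus by accumulative TF-IDF
#'
#' Every document is scored by [a_tf_idf()] and sorted by descending score;
#' ties are broken by ascending `doc_id` so rankings are deterministic.
#'
#' @param corpus A `concept_corpus`.
#' @param query A [concept_query()] or character vector.
#' @return A `ranked_list`: a tibble with columns `doc_id`, `score`, `rank`.
#' @seealso [rank_by_profile()] for feedback rounds.
#' @export
rank_initial <- function(corpus, query) {
  stopifnot(inherits(corpus, "concept_corpus"))
  query <- as_query(query)
  new_ranked_list(rank_entries(atfidf_scores(corpus, query)), scoring = "a_tf_idf")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list (%s): %d documents>\n",
              attr(x, "scoring") %||% "?", nrow(x)))
  NextMethod()
}

# doc ids of the top-n entries of a ranked list
top_ids <- function(ranked, n = nrow(ranked)) {
  utils::head(ranked$doc_id, n)
}
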