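#' Pool user-selected documents into a feedback transaction set
#'
#' Relevance feedback is mined at the sentence level: each sentence of each
#' selected document is one transaction, pooled in document order then
#' sentence order, no matter how many documents were selected. Empty sentences
#' are kept -- they are transactions with zero counts and contribute to the
#' transaction count N.
#'
#' @param corpus A `concept_corpus`.
#' @param doc_ids Character vector of selected document ids (duplicates
#'   collapsed, order preserved).
#' @return A `feedback_set` with fields `source_doc_ids`, `sentences` and
#'   `n_transactions`.
#' @export
feedback_set <- function(corpus, doc_ids) {
  stopifnot(inherits(corpus, "concept_corpus"))
  doc_ids <- unique(as.character(doc_ids))
  if (length(doc_ids) == 0L) {
    abort("no feedback provided")
  }
  docs <- lapply(doc_ids, function(id) corpus_doc(corpus, id))
  sentences <- unlist(lapply(docs, `[[`, "sentences"), recursive = FALSE)
  new_feedback_set(doc_ids, sentences %||% list())
}

new_feedback_set <- function(source_doc_ids, sentences) {
  if (length(sentences) == 0L) {
    abort("feedback set has no sentences")
  }
  structure(
    list(source_doc_ids = source_doc_ids,
         sentences = sentences,
         n_transactions = length(sentences)),
    class = "feedback_set"
  )
}

# a document mined against itself: its own sentences are the transactions and
# N is its own sentence count
document_transactions <- function(doc) {
  new_feedback_set(doc$doc_id, doc$sentences)
}

as_feedback_set <- function(x) {
  if (inherits(x, "feedback_set")) {
    x
  } else if (inherits(x, "concept_document")) {
    document_transactions(x)
  } else {
    abort("expected a feedback_set or a concept_document")
  }
}

#' @export
print.feedback_set <- function(x, ...) {
  cat(sprintf("<feedback_set: %d transaction(s) from %d document(s)>\n",
              x$n_transactions, length(x$source_doc_ids)))
  invisible(x)
}

#' Partial count of a query in a sentence
#'
#' Number of distinct query concepts present in the sentence divided by the
#' query size. Membership is set-based: within-sentence multiplicity is
#' ignored. This fractional count is what makes the interest measure usable
#' for multi-concept queries, whose concepts rarely co-occur in full within
#' one sentence.
#'
#' @param sentence Character vector of concept tokens.
#' @param query A [concept_query()] or character vector.
#' @return A value in \[0, 1\].
#' @examples
#' partial_count_query(c("1", "3", "4", "3", "5"), c("3", "2", "6")) # 1/3
#' @export
partial_count_query <- function(sentence, query) {
  query <- as_query(query)
  sum(query %in% sentence) / length(query)
}

#' Binary count of a concept in a sentence
#'
#' @param sentence Character vector of concept tokens.
#' @param concept Single concept token.
#' @return 1 if the sentence contains the concept, else 0.
#' @export
binary_count_concept <- function(sentence, concept) {
  as.integer(concept %in% sentence)
}

#' Joint partial count of a query and a concept in a sentence
#'
#' Product of [partial_count_query()] and [binary_count_concept()]: the
#' query's partial count if the concept is present, 0 otherwise.
#'
#' @inheritParams partial_count_query
#' @param concept Single concept token.
#' @return A value in \[0, 1\].
#' @export
joint_partial_count <- function(sentence, query, concept) {
  partial_count_query(sentence, query) * binary_count_concept(sentence, concept)
}

#' Weighted frequency of a query over a feedback set
#'
#' Sum of the query's partial counts over all transactions.
#'
#' @param z A [feedback_set()] or `concept_document`.
#' @param query A [concept_query()] or character vector.
#' @return Non-negative real.
#' @export
weighted_frequency_query <- function(z, query) {
  z <- as_feedback_set(z)
  query <- as_query(query)
  sum(vapply(z$sentences, partial_count_query, numeric(1), query = query))
}

#' Frequency of a concept over a feedback set
#'
#' Number of transactions containing the concept.
#'
#' @inheritParams weighted_frequency_query
#' @param concept Single concept token.
#' @return Non-negative integer.
#' @export
frequency_concept <- function(z, concept) {
  z <- as_feedback_set(z)
  sum(vapply(z$sentences, function(s) concept %in% s, logical(1)))
}

#' Weighted joint frequency of a query and a concept over a feedback set
#'
#' Sum of [joint_partial_count()] over all transactions.
#'
#' @inheritParams frequency_concept
#' @param query A [concept_query()] or character vector.
#' @return Non-negative real.
#' @export
weighted_joint_frequency <- function(z, query, concept) {
  z <- as_feedback_set(z)
  query <- as_query(query)
  sum(vapply(z$sentences, joint_partial_count, numeric(1),
             query = query, concept = concept))
}

#' Weighted interest of an association rule query -> concept
#'
#' The interest (lift) measure extended with fractional query counts:
#' `N * f_joint^w / (f_Q^w * f_c)` over the N transactions of the feedback
#' set. Values above 1 indicate association beyond the independence baseline.
#' When the query touches no transaction (`f_Q^w = 0`) the measure is defined
#' as 0: there is no evidence of association and division by zero is avoided.
#'
#' With a single-concept query the fractional counts become binary and the
#' measure reduces to classic interest/lift.
#'
#' @inheritParams frequency_concept
#' @param query A [concept_query()] or character vector.
#' @return Non-negative real.
#' @examples
#' doc <- concept_document("d1", list(
#'   c("1", "3", "4", "3", "5"), c("4", "5", "5", "1"),
#'   c("3", "5", "1", "3", "1", "6"), c("1", "5", "4", "4", "1"),
#'   c("5", "2", "4", "6", "2")
#' ))
#' weighted_interest(doc, c("3", "2", "6"), "1") # 0.75
#' @export
weighted_interest <- function(z, query, concept) {
  z <- as_feedback_set(z)
  query <- as_query(query)
  f_c <- frequency_concept(z, concept)
  if (f_c == 0L) {
    abort(sprintf("concept '%s' not in feedback", concept))
  }
  f_q_w <- weighted_frequency_query(z, query)
  if (f_q_w == 0) {
    return(0)
  }
  z$n_transactions * weighted_joint_frequency(z, query, concept) / (f_q_w * f_c)
}

#' Mine all query -> concept association rules from a feedback set
#'
#' Forms one rule per distinct concept in the feedback set and scores each by
#' [weighted_interest()]. The implementation is vectorised over a
#' sentence-by-concept membership matrix; it is exact, not approximate.
#'
#' @inheritParams weighted_frequency_query
#' @return A tibble with one row per rule, columns `concept`, `f_c`,
#'   `f_joint_w`, `f_q_w`, `interest_w`, ordered by descending `interest_w`
#'   (ties: descending `f_joint_w`, then ascending concept).
#' @export
mine_associations <- function(z, query) {
  z <- as_feedback_set(z)
  query <- as_query(query)
  sent_sets <- lapply(z$sentences, unique)
  concepts <- sort(unique(unlist(sent_sets, use.names = FALSE)))
  if (length(concepts) == 0L) {
    abort("feedback set contains no concepts")
  }
  n_sent <- length(sent_sets)
  # logical membership matrix: sentence x concept
  j <- match(unlist(sent_sets, use.names = FALSE), concepts)
  i <- rep(seq_len(n_sent), lengths(sent_sets))
  m <- matrix(FALSE, nrow = n_sent, ncol = length(concepts))
  m[cbind(i, j)] <- TRUE
  cnt_q <- vapply(sent_sets, function(s) sum(query %in% s), numeric(1)) /
    length(query)
  f_q_w <- sum(cnt_q)
  f_c <- colSums(m)
  f_joint_w <- as.numeric(crossprod(m, cnt_q))
  interest_w <- if (f_q_w == 0) {
    rep(0, length(concepts))
  } else {
    z$n_transactions * f_joint_w / (f_q_w * f_c)
  }
  tibble(concept = concepts,
         f_c = as.integer(f_c),
         f_joint_w = f_joint_w,
         f_q_w = f_q_w,
         interest_w = interest_w) |>
    dplyr::arrange(dplyr::desc(.data$interest_w),
                   dplyr::desc(.data$f_joint_w),
                   .data$concept)
}

#' Build a k-profile from feedback or from a single document
#'
#' The top k concepts by weighted interest against the query form a profile
#' of the user's intention (when built from feedback) or of a document's
#' relevance to the query (when built from the document itself; the
#' document's own sentences are the transactions and N is its sentence
#' count). All concepts are ranked and truncated at k; no interest floor is
#' applied.
#'
#' @param x A [feedback_set()] or a `concept_document`.
#' @param query A [concept_query()] or character vector.
#' @param k Maximum profile depth (>= 1).
#' @return A `k_profile`: a tibble with columns `rank`, `concept`,
#'   `interest_w` and attributes `query`, `k` and `n_transactions`.
#' @examples
#' doc <- concept_document("d1", list(c("1", "2", "3"), c("2", "3")))
#' build_k_profile(doc, "2", k = 2)
#' @export
build_k_profile <- function(x, query, k = 30L) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  query <- as_query(query)
  z <- as_feedback_set(x)
  if (length(unlist(z$sentences, use.names = FALSE)) == 0L) {
    # concept-free input profiles to nothing rather than erroring
    return(new_k_profile(
      tibble(rank = integer(0), concept = character(0), interest_w = numeric(0)),
      query = query, k = as.integer(k), n_transactions = z$n_transactions
    ))
  }
  scores <- mine_associations(z, query)
  top <- utils::head(scores, k)
  new_k_profile(
    tibble(rank = seq_len(nrow(top)),
           concept = top$concept,
           interest_w = top$interest_w),
    query = query, k = as.integer(k),
    n_transactions = z$n_transactions
  )
}

new_k_profile <- function(entries, query, k, n_transactions) {
  structure(as_tibble(entries),
            query = query, k = k, n_transactions = n_transactions,
            class = c("k_profile", class(as_tibble(entries))))
}

#' Concepts of a profile in rank order
#' @param profile A `k_profile`.
#' @return Character vector.
#' @export
profile_concepts <- function(profile) {
  stopifnot(inherits(profile, "k_profile"))
  profile$concept
}

#' @export
print.k_profile <- function(x, ...) {
  cat(sprintf("<k_profile: %d of k=%d concepts for query {%s}>\n",
              nrow(x), attr(x, "k"),
              paste(attr(x, "query"), collapse = ", ")))
  NextMethod()
}

#' Serialize a k-profile to JSON
#'
#' @param profile A `k_profile`.
#' @param path Optional path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_profile_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "k_profile"))
  obj <- list(
    query = as.character(attr(profile, "query")),
    k = jsonlite::unbox(attr(profile, "k")),
    concepts = purrr::map2(profile$concept, profile$interest_w, function(c, iw) {
      list(concept = jsonlite::unbox(c), iw = jsonlite::unbox(iw))
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) {
    return(as.character(js))
  }
  writeLines(js, path)
  invisible(path)
}
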