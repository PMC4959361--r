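#' Retain user-selected documents in the next round's top list
#'
#' After re-ranking, some documents the user marked relevant may have fallen
#' out of the new top list. Those missing selections replace the lowest-ranked
#' documents of the new top list that were not themselves selected: the new
#' list is walked from its end, each non-selected document is replaced by the
#' last not-yet-placed missing selection, and selected documents already
#' present are skipped. Documents that are not displaced keep their relative
#' order.
#'
#' @param prev_top Ordered doc ids of the previous round's top list.
#' @param selected Doc ids the user marked relevant (must all be in
#'   `prev_top`).
#' @param next_top Ordered doc ids of the re-ranked top list; same length as
#'   `prev_top`.
#' @return Ordered doc ids of the adjusted top list, same length as
#'   `next_top`, containing every selected document.
#' @examples
#' retain_feedback(
#'   prev_top = paste0("d", 1:10),
#'   selected = c("d2", "d4", "d5", "d9"),
#'   next_top = c("d2", "d13", "d11", "d7", "d14", "d1", "d10", "d3", "d5", "d12")
#' )
#' @export
retain_feedback <- function(prev_top, selected, next_top) {
  prev_top <- as.character(prev_top)
  selected <- unique(as.character(selected))
  next_top <- as.character(next_top)
  if (!all(selected %in% prev_top)) {
    abort("every selected document must be in the previous top list")
  }
  if (length(next_top) != length(prev_top)) {
    abort("next_top must have the same length as prev_top")
  }
  # keep selections in their previous-round rank order
  selected <- selected[order(match(selected, prev_top))]
  xi <- selected[!selected %in% next_top]
  out <- next_top
  for (i in rev(seq_along(out))) {
    if (length(xi) == 0L) {
      break
    }
    if (!out[i] %in% selected) {
      out[i] <- xi[length(xi)]
      xi <- xi[-length(xi)]
    }
  }
  if (length(xi) > 0L) {
    abort("cannot retain all feedback: too few replaceable slots")
  }
  out
}

#' Start a multi-round search session
#'
#' A session holds the corpus, the query, the review-window size chi (how
#' many top documents the user reviews each round), the profile depth k and
#' the RBO decay phi, plus the per-round history of rankings and selections.
#' Sessions are immutable values: [run_initial()] and [submit_feedback()]
#' return updated copies.
#'
#' @param corpus A `concept_corpus`.
#' @param query A [concept_query()] or character vector.
#' @param chi Size of the top list the user reviews (default 10).
#' @param k Profile depth for association mining (default 30).
#' @param phi RBO weight-decay parameter (default 0.9).
#' @return A `search_session`.
#' @export
search_session <- function(corpus, query, chi = 10L, k = 30L, phi = 0.9) {
  stopifnot(inherits(corpus, "concept_corpus"))
  query <- as_query(query)
  stopifnot(is.numeric(chi), length(chi) == 1L, chi >= 1)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  check_phi(phi)
  structure(
    list(corpus = corpus, query = query,
         chi = as.integer(chi), k = as.integer(k), phi = phi,
         round = 0L, history = list(), doc_profiles = NULL),
    class = "search_session"
  )
}

#' @export
print.search_session <- function(x, ...) {
  cat(sprintf(
    "<search_session: query {%s}, chi=%d, k=%d, phi=%g, %d round(s) ranked>\n",
    paste(x$query, collapse = ", "), x$chi, x$k, x$phi, length(x$history)))
  invisible(x)
}

#' Run the initial accumulative-TF-IDF search of a session
#'
#' @param session A [search_session()] that has not been run yet.
#' @return The session with the initial ranking recorded as round 0.
#' @export
run_initial <- function(session) {
  stopifnot(inherits(session, "search_session"))
  if (length(session$history) > 0L) {
    abort("session already has an initial ranking")
  }
  ranking <- rank_initial(session$corpus, session$query)
  session$history <- list(list(ranking = ranking, selected = character(0)))
  session
}

#' Ranking of a given round
#'
#' @param session A `search_session`.
#' @param round Round number: 0 is the initial search, 1 the first feedback
#'   round, and so on. Defaults to the latest round.
#' @return A `ranked_list`.
#' @export
session_ranking <- function(session, round = NULL) {
  stopifnot(inherits(session, "search_session"))
  round <- round %||% (length(session$history) - 1L)
  if (length(session$history) == 0L || round < 0L ||
      round > length(session$history) - 1L) {
    abort(sprintf("no ranking for round %s", round))
  }
  session$history[[round + 1L]]$ranking
}

#' Top-chi doc ids of the current round
#'
#' @param session A `search_session`.
#' @param n Number of top documents; defaults to the session's chi.
#' @return Character vector of doc ids.
#' @export
session_top <- function(session, n = NULL) {
  top_ids(session_ranking(session), n %||% session$chi)
}

#' Submit relevance feedback and run the next-round search
#'
#' The selected documents (all within the current top-chi window) are pooled
#' into one transaction set, mined into a k-profile against the query, and
#' every document is re-ranked by RBO similarity to that profile. Selections
#' are then retained in the new top-chi window via [retain_feedback()].
#' Each round is mined from that round's selection only; past selections stay
#' in the history for audit.
#'
#' @param session A `search_session` with at least the initial ranking.
#' @param selected Doc ids chosen from the current top-chi (duplicates
#'   collapsed).
#' @return The session advanced by one round.
#' @export
submit_feedback <- function(session, selected) {
  stopifnot(inherits(session, "search_session"))
  if (length(session$history) == 0L) {
    abort("run_initial() must be called before submitting feedback")
  }
  selected <- unique(as.character(selected))
  if (length(selected) == 0L) {
    abort("no feedback provided")
  }
  prev_top <- session_top(session)
  if (!all(selected %in% prev_top)) {
    abort(sprintf("selection outside the current top-%d: %s", session$chi,
                  paste(setdiff(selected, prev_top), collapse = ", ")))
  }
  z <- feedback_set(session$corpus, selected)
  profile <- build_k_profile(z, session$query, k = session$k)
  if (is.null(session$doc_profiles)) {
    session$doc_profiles <- document_profiles(session$corpus, session$query)
  }
  reranked <- rank_by_profile(session$corpus, profile,
                              phi = session$phi, k = session$k,
                              doc_profiles = session$doc_profiles)
  chi <- min(session$chi, nrow(reranked))
  adjusted_top <- retain_feedback(utils::head(prev_top, chi), selected,
                                  top_ids(reranked, chi))
  new_order <- c(adjusted_top, setdiff(reranked$doc_id, adjusted_top))
  adjusted <- reranked[match(new_order, reranked$doc_id), ]
  adjusted$rank <- seq_len(nrow(adjusted))
  adjusted <- new_ranked_list(adjusted, scoring = "rbo")
  session$history[[length(session$history)]]$selected <- selected
  session$history[[length(session$history) + 1L]] <-
    list(ranking = adjusted, selected = character(0))
  session$round <- session$round + 1L
  session
}
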