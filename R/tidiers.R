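#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a k-profile
#'
#' @param x A `k_profile`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `concept`, `interest_w`.
#' @export
tidy.k_profile <- function(x, ...) {
  tibble(rank = x$rank, concept = x$concept, interest_w = x$interest_w)
}

#' One-row summary of a k-profile
#'
#' @param x A `k_profile`.
#' @param ... Unused.
#' @return A tibble with `k`, `n_concepts`, `n_transactions`, `query_size`,
#'   `max_interest`.
#' @export
glance.k_profile <- function(x, ...) {
  tibble(k = attr(x, "k"),
         n_concepts = nrow(x),
         n_transactions = attr(x, "n_transactions"),
         query_size = length(attr(x, "query")),
         max_interest = if (nrow(x)) max(x$interest_w) else NA_real_)
}

#' Tidy a search session's history
#'
#' @param x A `search_session`.
#' @param ... Unused.
#' @return A tibble with one row per (round, document): `round`, `doc_id`,
#'   `rank`, `score`, `selected`.
#' @export
tidy.search_session <- function(x, ...) {
  purrr::imap_dfr(x$history, function(h, i) {
    dplyr::mutate(as_tibble(h$ranking),
                  round = i - 1L,
                  selected = .data$doc_id %in% h$selected)
  })[c("round", "doc_id", "rank", "score", "selected")]
}

#' One-row summary of a search session
#'
#' @param x A `search_session`.
#' @param ... Unused.
#' @return A tibble with `rounds`, `chi`, `k`, `phi`, `n_docs`, `query_size`.
#' @export
glance.search_session <- function(x, ...) {
  tibble(rounds = length(x$history), chi = x$chi, k = x$k, phi = x$phi,
         n_docs = nrow(x$corpus), query_size = length(x$query))
}

#' Tidy a simulated-user run
#'
#' @param x A `user_simulation`.
#' @param ... Unused.
#' @return The per-round metrics tibble.
#' @export
tidy.user_simulation <- function(x, ...) {
  x$metrics
}

#' One-row summary of a simulated-user run
#'
#' @param x A `user_simulation`.
#' @param ... Unused.
#' @return A tibble with `topic_id`, `rounds`, `feedback_capable`, and the
#'   final round's `ap10`/`ap20`.
#' @export
glance.user_simulation <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  tibble(topic_id = last$topic_id,
         rounds = nrow(x$metrics),
         feedback_capable = x$feedback_capable,
         final_ap10 = last$ap10,
         final_ap20 = last$ap20)
}
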