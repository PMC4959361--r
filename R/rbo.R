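check_rbo_list <- function(x, what) {
  x <- if (inherits(x, "k_profile")) profile_concepts(x) else as.character(x)
  if (anyDuplicated(x)) {
    abort(sprintf("%s contains duplicate concepts", what))
  }
  x
}

check_phi <- function(phi) {
  stopifnot(is.numeric(phi), length(phi) == 1L)
  if (!(phi > 0 && phi < 1)) {
    abort("phi must lie strictly between 0 and 1")
  }
  phi
}

#' Per-depth decomposition of truncated rank-biased overlap
#'
#' At each depth d the two lists are truncated to their top-d concepts (or to
#' the whole list when it is shorter -- incomplete rankings are handled by
#' comparing whatever prefix is available), the overlap is the size of the
#' intersection of the prefixes, the agreement is overlap/d, and the weighted
#' term is `phi^(d-1) * agreement`. The similarity is `(1 - phi)` times the
#' sum of the weighted terms.
#'
#' @param a,b Ranked concept lists: character vectors or `k_profile`s, no
#'   internal duplicates.
#' @param phi Geometric weight-decay parameter in (0, 1); smaller values are
#'   more top-weighted.
#' @param k Evaluation depth; defaults to the longer list's length.
#' @return A tibble with columns `depth`, `overlap`, `agreement`, `term`.
#' @seealso [rbo_similarity()]
#' @export
rbo_agreement_terms <- function(a, b, phi = 0.9, k = NULL) {
  a <- check_rbo_list(a, "a")
  b <- check_rbo_list(b, "b")
  check_phi(phi)
  k <- as.integer(k %||% max(length(a), length(b), 1L))
  stopifnot(k >= 1L)
  depths <- seq_len(k)
  overlap <- vapply(depths, function(d) {
    length(intersect(utils::head(a, d), utils::head(b, d)))
  }, integer(1))
  agreement <- overlap / depths
  tibble(depth = depths,
         overlap = overlap,
         agreement = agreement,
         term = phi^(depths - 1) * agreement)
}

#' Truncated rank-biased overlap between two ranked concept lists
#'
#' Top-weighted similarity `(1 - phi) * sum_{d=1..k} phi^(d-1) * overlap_d/d`
#' between two (possibly incomplete) rankings, with geometric weight decay by
#' depth. All arithmetic is done at full precision; round only for reporting.
#' Note the truncated form cannot reach 1: two identical length-k lists score
#' `1 - phi^k`.
#'
#' @inheritParams rbo_agreement_terms
#' @return A value in \[0, 1\].
#' @examples
#' rbo_similarity(c("2", "3", "1", "6", "8"), c("2", "1", "4", "3", "5"),
#'                phi = 0.9, k = 5) # ~0.293
#' @export
rbo_similarity <- function(a, b, phi = 0.9, k = NULL) {
  terms <- rbo_agreement_terms(a, b, phi = phi, k = k)
  (1 - phi) * sum(terms$term)
}

#' Rank-order concept profiles of every document in a corpus
#'
#' Computes, once per (corpus, query), the full weighted-interest ordering of
#' each document's concepts. The orderings do not depend on the profile depth
#' k or on any feedback, so they can be cached and truncated to any k by
#' [rank_by_profile()] -- this is what makes multi-round feedback and
#' k-sweeps cheap.
#'
#' @param corpus A `concept_corpus`.
#' @param query A [concept_query()] or character vector.
#' @return Named list (by doc_id) of character vectors: each document's
#'   concepts in descending weighted-interest order.
#' @export
document_profiles <- function(corpus, query) {
  stopifnot(inherits(corpus, "concept_corpus"))
  query <- as_query(query)
  profs <- lapply(seq_len(nrow(corpus)), function(i) {
    sents <- corpus$sentences[[i]]
    if (length(unlist(sents, use.names = FALSE)) == 0L) {
      return(character(0))
    }
    mine_associations(new_feedback_set(corpus$doc_id[[i]], sents), query)$concept
  })
  names(profs) <- corpus$doc_id
  profs
}

#' Re-rank a corpus by rank-biased overlap against a feedback profile
#'
#' Every document's own k-profile (same query, same k) is compared with the
#' feedback profile by [rbo_similarity()]; documents are ordered by descending
#' similarity with the same deterministic tie-break as [rank_initial()].
#'
#' @param corpus A `concept_corpus`.
#' @param feedback_profile A `k_profile` built from the user's feedback.
#' @param phi RBO weight-decay parameter.
#' @param k Profile depth; defaults to the feedback profile's k.
#' @param doc_profiles Optional cache from [document_profiles()] for the same
#'   corpus and query; computed on the fly when absent.
#' @return A `ranked_list` tibble (`doc_id`, `score`, `rank`).
#' @export
rank_by_profile <- function(corpus, feedback_profile, phi = 0.9, k = NULL,
                            doc_profiles = NULL) {
  stopifnot(inherits(corpus, "concept_corpus"),
            inherits(feedback_profile, "k_profile"))
  if (nrow(feedback_profile) == 0L) {
    abort("no feedback profile")
  }
  check_phi(phi)
  k <- as.integer(k %||% attr(feedback_profile, "k"))
  query <- attr(feedback_profile, "query")
  fb <- utils::head(profile_concepts(feedback_profile), k)
  profs <- doc_profiles %||% document_profiles(corpus, query)
  scores <- vapply(corpus$doc_id, function(id) {
    rbo_similarity(fb, utils::head(profs[[id]], k), phi = phi, k = k)
  }, numeric(1))
  new_ranked_list(
    rank_entries(tibble(doc_id = corpus$doc_id, score = unname(scores))),
    scoring = "rbo"
  )
}
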