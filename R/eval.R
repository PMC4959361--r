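ranking_ids <- function(ranked) {
  if (inherits(ranked, "data.frame")) {
    as.character(ranked$doc_id)
  } else {
    as.character(ranked)
  }
}

#' Average precision at a cutoff
#'
#' Mean of precision-at-rank over the ranks (within the cutoff) at which
#' relevant documents occur. The denominator is the number of relevant
#' documents retrieved within the cutoff, so AP@N is 1 whenever every
#' relevant document found in the top N sits in a perfect prefix; a top-N
#' list holding no relevant document scores 0.
#'
#' @param ranked A `ranked_list` (or any data frame with a `doc_id` column)
#'   or a character vector of doc ids in rank order.
#' @param relevant Character vector of relevant doc ids.
#' @param cutoff Evaluate the top `cutoff` positions only (default: the whole
#'   list).
#' @return A value in \[0, 1\].
#' @examples
#' average_precision(c("a", "b", "c", "d"), relevant = "d", cutoff = 10) # 0.25
#' @export
average_precision <- function(ranked, relevant, cutoff = NULL) {
  ids <- ranking_ids(ranked)
  if (length(ids) == 0L) {
    abort("empty ranking")
  }
  cutoff <- cutoff %||% length(ids)
  stopifnot(cutoff >= 1)
  top <- utils::head(ids, cutoff)
  hits <- top %in% relevant
  if (!any(hits)) {
    return(0)
  }
  prec_at <- cumsum(hits) / seq_along(hits)
  mean(prec_at[hits])
}

#' Mean average precision over a set of runs
#'
#' @param runs Either a data frame with list columns `ranked` and `relevant`
#'   (one row per topic) or a list of `list(ranked=, relevant=)` pairs.
#' @param cutoff Passed to [average_precision()].
#' @return Arithmetic mean of the per-topic average precisions.
#' @export
mean_average_precision <- function(runs, cutoff = NULL) {
  if (inherits(runs, "data.frame")) {
    runs <- purrr::pmap(runs[c("ranked", "relevant")], list)
  }
  stopifnot(is.list(runs), length(runs) >= 1L)
  aps <- vapply(runs, function(r) {
    average_precision(r$ranked, r$relevant, cutoff = cutoff)
  }, numeric(1))
  mean(aps)
}

grade_levels <- c("NOT", "POSSIBLY", "DEFINITELY")

#' Read TREC-style relevance judgments
#'
#' Whitespace-separated qrels lines `topic_id 0 doc_id grade`, with grades
#' encoded 0 = NOT, 1 = POSSIBLY, 2 = DEFINITELY (the grade names themselves
#' are also accepted). Missing (topic, doc) pairs are treated as NOT
#' relevant.
#'
#' @param path Path to a qrels file.
#' @return A `relevance_judgments` tibble with columns `topic_id`, `doc_id`
#'   and `grade` (factor NOT/POSSIBLY/DEFINITELY).
#' @seealso [relevant_docs()], [write_judgments()]
#' @export
read_judgments <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("qrels file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("empty qrels file")
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed qrels line %d", bad[1]))
  }
  m <- do.call(rbind, fields)
  grade_raw <- m[, 4]
  grade <- ifelse(grade_raw %in% c("0", "1", "2"),
                  grade_levels[as.integer(grade_raw) + 1L],
                  grade_raw)
  unknown <- !grade %in% grade_levels
  if (any(unknown)) {
    abort(sprintf("unknown grade token '%s' in qrels", grade_raw[unknown][1]))
  }
  new_judgments(tibble(
    topic_id = m[, 1],
    doc_id = m[, 3],
    grade = factor(grade, levels = grade_levels)
  ))
}

new_judgments <- function(x) {
  structure(as_tibble(x), class = c("relevance_judgments", class(as_tibble(x))))
}

#' Write relevance judgments as a qrels file
#'
#' @param judgments A `relevance_judgments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_judgments <- function(judgments, path) {
  stopifnot(all(c("topic_id", "doc_id", "grade") %in% names(judgments)))
  grade_code <- match(as.character(judgments$grade), grade_levels) - 1L
  writeLines(sprintf("%s 0 %s %d", judgments$topic_id, judgments$doc_id,
                     grade_code), path)
  invisible(path)
}

#' Binary relevant-document set for a topic
#'
#' Two gold standards are supported: `"possibly+"` counts POSSIBLY and
#' DEFINITELY passages as relevant; `"definitely-only"` restricts to highly
#' relevant documents.
#'
#' @param judgments A `relevance_judgments` tibble.
#' @param topic_id Topic identifier.
#' @param mode `"possibly+"` (default) or `"definitely-only"`.
#' @return Character vector of relevant doc ids.
#' @export
relevant_docs <- function(judgments, topic_id,
                          mode = c("possibly+", "definitely-only")) {
  mode <- match.arg(mode)
  keep <- if (mode == "possibly+") c("POSSIBLY", "DEFINITELY") else "DEFINITELY"
  unique(judgments$doc_id[judgments$topic_id == topic_id &
                            as.character(judgments$grade) %in% keep])
}

#' Simulate a user doing multi-round relevance feedback
#'
#' The simulated user reviews the top chi documents of each round and selects
#' every judged-relevant document among them as feedback -- the standard
#' top-10/top-20 feedback protocol. If the initial top-chi holds no relevant
#' document the topic is marked non-feedback-capable and the simulation stops
#' after the initial round (such topics are excluded from later-round
#' aggregate MAP by the caller). Later rounds likewise stop when no relevant
#' document remains in the window.
#'
#' @param corpus A `concept_corpus`.
#' @param query A [concept_query()] or character vector.
#' @param relevant Character vector of relevant doc ids for the topic (derive
#'   from qrels with [relevant_docs()]).
#' @param topic_id Label used in the metrics table.
#' @param chi Review-window size (default 10).
#' @param rounds Total number of ranked lists including the initial search
#'   (default 3: initial, 2nd round, 3rd round).
#' @param k Profile depth.
#' @param phi RBO weight-decay parameter.
#' @return A `user_simulation`: list with `metrics` (tibble `topic_id`,
#'   `round`, `rel_in_top10`, `rel_in_top20`, `ap10`, `ap20`),
#'   `feedback_capable`, `rankings` (list of `ranked_list`s, round 0 first)
#'   and the final `session`.
#' @export
simulate_user <- function(corpus, query, relevant, topic_id = "topic",
                          chi = 10L, rounds = 3L, k = 30L, phi = 0.9) {
  stopifnot(rounds >= 1L)
  relevant <- unique(as.character(relevant))
  session <- run_initial(search_session(corpus, query, chi = chi, k = k,
                                        phi = phi))
  metric_row <- function(round, ranking) {
    tibble(
      topic_id = topic_id, round = round,
      rel_in_top10 = sum(top_ids(ranking, 10L) %in% relevant),
      rel_in_top20 = sum(top_ids(ranking, 20L) %in% relevant),
      ap10 = average_precision(ranking, relevant, cutoff = 10L),
      ap20 = average_precision(ranking, relevant, cutoff = 20L)
    )
  }
  metrics <- metric_row(0L, session_ranking(session, 0L))
  feedback_capable <- TRUE
  for (r in seq_len(rounds - 1L)) {
    selection <- intersect(session_top(session), relevant)
    if (length(selection) == 0L) {
      if (r == 1L) feedback_capable <- FALSE
      break
    }
    session <- submit_feedback(session, selection)
    metrics <- dplyr::bind_rows(metrics,
                                metric_row(r, session_ranking(session, r)))
  }
  structure(
    list(metrics = metrics,
         feedback_capable = feedback_capable,
         rankings = lapply(seq_along(session$history) - 1L,
                           function(r) session_ranking(session, r)),
         session = session),
    class = "user_simulation"
  )
}

#' @export
print.user_simulation <- function(x, ...) {
  cat(sprintf("<user_simulation: %d round(s)%s>\n",
              nrow(x$metrics),
              if (x$feedback_capable) "" else ", not feedback-capable"))
  print(x$metrics)
  invisible(x)
}

#' Per-round metrics report with a MAP summary row
#'
#' Binds the metric tables of several simulated topics and appends one
#' summary row per round with the mean average precision over the
#' feedback-capable topics that reached that round.
#'
#' @param simulations List of `user_simulation` objects.
#' @return A tibble in the per-topic metrics layout, with `topic_id = "MAP"`
#'   summary rows.
#' @export
metrics_report <- function(simulations) {
  stopifnot(length(simulations) >= 1L)
  per_topic <- dplyr::bind_rows(lapply(simulations, `[[`, "metrics"))
  summary <- per_topic |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(topic_id = "MAP",
                     rel_in_top10 = NA_integer_,
                     rel_in_top20 = NA_integer_,
                     ap10 = mean(.data$ap10),
                     ap20 = mean(.data$ap20),
                     .groups = "drop")
  dplyr::bind_rows(per_topic, summary[names(per_topic)])
}
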