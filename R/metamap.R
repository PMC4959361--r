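#' Construct a concept query
#'
#' A query is a set of unique concept tokens describing the topic of interest;
#' duplicates are collapsed at construction (first occurrence kept).
#'
#' @param concepts Character vector of concept tokens.
#' @return Character vector of class `concept_query` with unique tokens.
#' @examples
#' concept_query(c("3", "2", "6", "2"))
#' @export
concept_query <- function(concepts) {
  concepts <- as.character(concepts)
  check_tokens(concepts, context = "query")
  concepts <- unique(concepts)
  if (length(concepts) == 0L) {
    abort("a query needs at least one concept")
  }
  structure(concepts, class = c("concept_query", "character"))
}

as_query <- function(x) {
  if (inherits(x, "concept_query")) x else concept_query(x)
}

#' Parse MetaMap-style concept-mapping output into a concept document
#'
#' Concept-mapping tools such as MetaMap segment an article into sentences and
#' phrases and map each phrase to candidate concepts, each with a match score
#' (0--1000). This parser reads a fielded dialect of such output: a sentence
#' delimiter line `#SENT`, a phrase header `#PHRASE<TAB>text`, and candidate
#' lines `score<TAB>CUI<TAB>name<TAB>[semantic type]` (the semantic-type field
#' is optional).
#'
#' Within each phrase occurrence, every candidate whose score is strictly
#' greater than `score_threshold` contributes its concept once (a phrase
#' mapping to the same concept through two high-scoring candidates yields the
#' concept once per occurrence); a phrase occurring m times in the input
#' contributes its concepts m times. Sentences in which no candidate clears
#' the threshold become empty sentences -- they are retained because they
#' still count as transactions in association mining.
#'
#' @param text The fielded output, as a single string or a character vector of
#'   lines.
#' @param score_threshold Minimum (exclusive) candidate score; defaults to
#'   500, the conventional operating point for curated extraction.
#' @param doc_id Identifier for the resulting document.
#' @return A [concept_document()]; one sentence per `#SENT` block.
#' @examples
#' txt <- c("#SENT", "#PHRASE\tcathepsin D", "1000\tC0007630\tCathepsin D\t[aapp]")
#' parse_metamap_output(txt)
#' @export
parse_metamap_output <- function(text, score_threshold = 500, doc_id = "metamap") {
  stopifnot(is.numeric(score_threshold), length(score_threshold) == 1L,
            score_threshold >= 0)
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  sentences <- list()
  cur <- NULL          # tokens of the current sentence
  phrase_seen <- FALSE # inside a phrase block?
  phrase_tokens <- character(0)
  flush_phrase <- function() {
    if (phrase_seen) {
      # deduplicate within one phrase occurrence
      cur <<- c(cur, unique(phrase_tokens))
    }
    phrase_tokens <<- character(0)
    phrase_seen <<- FALSE
  }
  flush_sentence <- function() {
    flush_phrase()
    if (!is.null(cur)) {
      sentences[[length(sentences) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) next
    if (line == "#SENT") {
      flush_sentence()
      cur <- character(0)
    } else if (startsWith(line, "#PHRASE")) {
      if (is.null(cur)) {
        abort(sprintf("phrase outside a sentence at line %d", ln))
      }
      flush_phrase()
      phrase_seen <- TRUE
    } else {
      if (is.null(cur) || !phrase_seen) {
        abort(sprintf("candidate line outside a phrase at line %d: '%s'", ln, line))
      }
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      score <- suppressWarnings(as.integer(parts[1]))
      if (length(parts) < 3L || is.na(score) || score < 0 || !nzchar(parts[2])) {
        abort(sprintf("unparseable candidate line at line %d: '%s'", ln, line))
      }
      if (score > score_threshold) {
        phrase_tokens <- c(phrase_tokens, parts[2])
      }
    }
  }
  flush_sentence()
  concept_document(doc_id, sentences)
}
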