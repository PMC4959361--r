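#' @importFrom rlang %||% abort .data
#' @importFrom tibble tibble as_tibble
NULL

# Concept tokens are opaque non-empty strings without whitespace; UMLS CUIs
# ("C0030567") and toy integer ids ("3") share one code path.
check_tokens <- function(tokens, context = "sentence") {
  if (length(tokens) == 0L) {
    return(invisible(character(0)))
  }
  tokens <- as.character(tokens)
  bad <- is.na(tokens) | !nzchar(tokens) | grepl("[[:space:]]", tokens)
  if (any(bad)) {
    abort(sprintf(
      "invalid concept token(s) in %s: %s",
      context, paste(utils::head(tokens[bad], 3L), collapse = ", ")
    ))
  }
  invisible(tokens)
}

#' Create a concept document
#'
#' A concept document is the unit of ranking and of relevance feedback: an
#' ordered list of sentences, each sentence an ordered multiset of concept
#' tokens (e.g. UMLS CUIs). Empty sentences are retained -- a sentence whose
#' source text mapped to no concepts still counts as a transaction when the
#' document is mined for associations.
#'
#' @param doc_id Non-empty string identifying the document.
#' @param sentences List of character vectors, one per sentence, in source
#'   order. A `character(0)` element is an empty sentence.
#' @return An object of class `concept_document`.
#' @examples
#' doc <- concept_document("d1", list(c("C1", "C2"), c("C2")))
#' doc_tokens(doc)
#' @export
concept_document <- function(doc_id, sentences = list()) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id)) {
    abort("doc_id must be a single non-empty string")
  }
  if (!is.list(sentences)) {
    abort("sentences must be a list of character vectors")
  }
  sentences <- lapply(seq_along(sentences), function(i) {
    s <- as.character(sentences[[i]])
    check_tokens(s, context = sprintf("document '%s', sentence %d", doc_id, i))
    s
  })
  structure(list(doc_id = doc_id, sentences = sentences),
            class = "concept_document")
}

#' @export
print.concept_document <- function(x, ...) {
  cat(sprintf("<concept_document '%s': %d sentences, %d tokens, %d unique concepts>\n",
              x$doc_id, length(x$sentences), length(doc_tokens(x)),
              length(doc_concepts(x))))
  invisible(x)
}

#' Flattened token multiset of a document
#'
#' @param doc A `concept_document`.
#' @return Character vector of all tokens in sentence order, multiplicity
#'   preserved.
#' @export
doc_tokens <- function(doc) {
  as.character(unlist(doc$sentences, use.names = FALSE))
}

#' Unique concept set of a document
#'
#' @param doc A `concept_document`.
#' @return Character vector of the distinct concepts, in first-occurrence
#'   order.
#' @export
doc_concepts <- function(doc) {
  unique(doc_tokens(doc))
}

#' Build a corpus of concept documents
#'
#' A corpus bundles documents with their document-frequency index, the count
#' of documents containing each concept (presence, not multiplicity), which
#' drives the IDF component of the initial ranking.
#'
#' @param documents A list of [concept_document()] objects, or a tibble with
#'   columns `doc_id` and `sentences` (a list column of lists of character
#'   vectors).
#' @return A `concept_corpus`: a tibble with columns `doc_id` and `sentences`
#'   and a `df_index` attribute (see [df_index()]).
#' @examples
#' corp <- concept_corpus(list(
#'   concept_document("d1", list(c("C1", "C2"))),
#'   concept_document("d2", list(c("C2", "C3"), "C2"))
#' ))
#' df_index(corp)
#' @export
concept_corpus <- function(documents) {
  if (inherits(documents, "data.frame")) {
    docs <- purrr::pmap(documents[c("doc_id", "sentences")],
                        function(doc_id, sentences) concept_document(doc_id, sentences))
  } else if (is.list(documents)) {
    docs <- lapply(documents, function(d) {
      if (!inherits(d, "concept_document")) {
        abort("documents must be concept_document objects")
      }
      d
    })
  } else {
    abort("documents must be a list or a data frame")
  }
  if (length(docs) == 0L) {
    abort("empty corpus: a corpus needs at least one document")
  }
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate doc_id: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble(doc_id = ids,
                sentences = lapply(docs, `[[`, "sentences"))
  attr(out, "df_index") <- build_df_index(out$sentences)
  class(out) <- c("concept_corpus", class(out))
  out
}

build_df_index <- function(sentence_lists) {
  per_doc <- lapply(sentence_lists, function(s) unique(unlist(s, use.names = FALSE)))
  all <- unlist(per_doc, use.names = FALSE)
  if (length(all) == 0L) {
    return(tibble(concept = character(0), df = integer(0)))
  }
  tab <- table(all)
  tibble(concept = names(tab), df = as.integer(tab)) |>
    dplyr::arrange(.data$concept)
}

#' Document-frequency index
#'
#' Number of documents each concept occurs in. For a `concept_corpus` the
#' index built at construction is returned; for a bare list of documents it is
#' computed on the fly.
#'
#' @param x A `concept_corpus` or a list of `concept_document` objects.
#' @return A tibble with columns `concept` and `df`, sorted by concept.
#' @export
df_index <- function(x) {
  if (inherits(x, "concept_corpus")) {
    return(attr(x, "df_index"))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "concept_document"))) {
    return(build_df_index(lapply(x, `[[`, "sentences")))
  }
  abort("x must be a concept_corpus or a list of concept_document objects")
}

#' @export
print.concept_corpus <- function(x, ...) {
  cat(sprintf("<concept_corpus: %d documents, %d indexed concepts>\n",
              nrow(x), nrow(df_index(x))))
  NextMethod()
}

#' Number of documents in a corpus
#' @param corpus A `concept_corpus`.
#' @return Integer count.
#' @export
n_docs <- function(corpus) {
  nrow(corpus)
}

#' Extract one document from a corpus
#'
#' @param corpus A `concept_corpus`.
#' @param doc_id Document identifier.
#' @return A `concept_document`.
#' @export
corpus_doc <- function(corpus, doc_id) {
  i <- match(doc_id, corpus$doc_id)
  if (is.na(i)) {
    abort(sprintf("no document '%s' in corpus", doc_id))
  }
  concept_document(corpus$doc_id[[i]], corpus$sentences[[i]])
}

#' Read a concept corpus from disk
#'
#' Two dialects are accepted and auto-detected. The line-based dialect uses a
#' header `#DOC<TAB>doc_id`, one sentence per following line (space-separated
#' concept tokens), and a blank line (or the next header / end of file) to end
#' the document. The JSON-Lines dialect has one object
#' `{"doc_id": ..., "sentences": [[tok, ...], ...]}` per line and is the only
#' dialect that can represent empty sentences.
#'
#' @param path Path to a corpus file (UTF-8).
#' @return A [concept_corpus()].
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("corpus file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    abort("empty corpus")
  }
  first <- lines[nzchar(trimws(lines))][1]
  if (startsWith(trimws(first), "{")) {
    read_corpus_jsonl(lines)
  } else {
    read_corpus_text(lines)
  }
}

read_corpus_text <- function(lines) {
  docs <- list()
  cur_id <- NULL
  cur_sentences <- NULL
  flush <- function() {
    if (!is.null(cur_id)) {
      docs[[length(docs) + 1L]] <<- concept_document(cur_id, cur_sentences)
    }
    cur_id <<- NULL
    cur_sentences <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) {           # blank line ends the document
      flush()
    } else if (startsWith(line, "#DOC")) {
      flush()
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L || parts[1] != "#DOC" || !nzchar(parts[2])) {
        abort(sprintf("malformed document header at line %d: '%s'", ln, line))
      }
      cur_id <- parts[2]
      cur_sentences <- list()
    } else {
      if (is.null(cur_id)) {
        abort(sprintf("sentence outside a document at line %d: '%s'", ln, line))
      }
      tokens <- strsplit(trimws(line), "[ ]+")[[1]]
      if (any(!nzchar(tokens))) {
        abort(sprintf("malformed sentence at line %d", ln))
      }
      cur_sentences[[length(cur_sentences) + 1L]] <- tokens
    }
  }
  flush()
  concept_corpus(docs)
}

read_corpus_jsonl <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) abort(sprintf("malformed JSON record at line %d: %s",
                                        i, conditionMessage(e)))
    )
    if (is.null(rec$doc_id) || is.null(rec$sentences)) {
      abort(sprintf("record at line %d lacks doc_id or sentences", i))
    }
    sentences <- lapply(rec$sentences, function(s) {
      as.character(unlist(s, use.names = FALSE))
    })
    concept_document(as.character(rec$doc_id), sentences)
  })
  concept_corpus(docs)
}

#' Write a concept corpus to disk
#'
#' The `"text"` dialect (default) is the line-based format described in
#' [read_corpus()]; it cannot encode an empty sentence (a blank line is a
#' document terminator), so corpora containing empty sentences must be written
#' with `format = "jsonl"`, which round-trips exactly.
#'
#' @param corpus A `concept_corpus`.
#' @param path Output path.
#' @param format `"text"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("text", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "concept_corpus"))
  if (format == "text") {
    has_empty <- any(vapply(corpus$sentences,
                            function(s) any(lengths(s) == 0L), logical(1)))
    if (has_empty) {
      abort(paste("the text dialect cannot represent an empty sentence;",
                  "use format = \"jsonl\""))
    }
    blocks <- purrr::map2(corpus$doc_id, corpus$sentences, function(id, sents) {
      c(paste0("#DOC\t", id),
        vapply(sents, paste, character(1), collapse = " "),
        "")
    })
    writeLines(unlist(blocks, use.names = FALSE), path, useBytes = TRUE)
  } else {
    recs <- purrr::map2_chr(corpus$doc_id, corpus$sentences, function(id, sents) {
      jsonlite::toJSON(
        list(doc_id = jsonlite::unbox(id), sentences = sents),
        auto_unbox = FALSE
      )
    })
    writeLines(recs, path, useBytes = TRUE)
  }
  invisible(path)
}
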