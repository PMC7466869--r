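# Readers and writers for the layered-document JSONL dialect and for
# TREC-style topic/qrels/run files, plus base-layer tokenization.
#
# Stopwords are never removed from stored token sequences (that would
# invalidate every recorded span); stopping is a query/scoring-vocabulary
# concern and is applied symmetrically at query time.

#' Tokenizer configuration
#'
#' Controls base-layer tokenization and the stopped scoring vocabulary.
#' The same configuration must be used at index and query time.
#'
#' @param lowercase Lowercase tokens? Default `TRUE`.
#' @param stopwords Character vector of stopwords (possibly empty). Stopwords
#'   stay in the stored base layer; they are only dropped when a stopped view
#'   is explicitly requested (see [tokenize()]) or when query-side stopping
#'   is enabled.
#' @param stemmer `"none"` (default) or `"suffix-s"`, a minimal plural
#'   stripper used by the synthetic lemma-layer generator.
#' @return A `tokenizer_config` object.
#' @export
tokenizer_config <- function(lowercase = TRUE, stopwords = character(),
                             stemmer = c("none", "suffix-s")) {
  stemmer <- match.arg(stemmer)
  structure(list(lowercase = isTRUE(lowercase),
                 stopwords = unique(as.character(stopwords)),
                 stemmer = stemmer),
            class = "tokenizer_config")
}

#' Default English stopword list
#'
#' A compact standard English list shipped with the package; pass a custom
#' vector (or a file read with `readLines()`) to [tokenizer_config()] to
#' override it.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "layerlm")
  readLines(path, warn = FALSE)
}

#' Tokenize text into base-layer tokens
#'
#' A simple rule tokenizer: split on whitespace, strip surrounding
#' punctuation from each piece, optionally lowercase. Internal punctuation
#' (hyphens, apostrophes) is retained. Deterministic; idempotent on its own
#' space-joined output.
#'
#' @param text A single string.
#' @param config A [tokenizer_config()].
#' @param stopped If `TRUE`, return the stopped view (stopwords removed).
#'   Default `FALSE`: the full token sequence, as stored in documents.
#' @return Character vector of tokens.
#' @examples
#' tokenize("pregnancy with preterm delivery", tokenizer_config())
#' @export
tokenize <- function(text, config = tokenizer_config(), stopped = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  pieces <- strsplit(trimws(text), "\\s+")[[1]]
  pieces <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", pieces)
  pieces <- pieces[nzchar(pieces)]
  if (config$lowercase) pieces <- tolower(pieces)
  if (stopped && length(config$stopwords)) {
    pieces <- pieces[!(pieces %in% config$stopwords)]
  }
  pieces
}

#' Minimal plural-s stemmer
#'
#' Strips a final "s" from tokens of length >= 4 that do not end in "ss".
#' Used only to derive synthetic lemma layers; retrieval defaults to
#' unstemmed text.
#'
#' @param tokens Character vector.
#' @return Character vector of the same length.
#' @export
stem_suffix_s <- function(tokens) {
  out <- tokens
  i <- nchar(out) >= 4L & grepl("s$", out) & !grepl("ss$", out)
  out[i] <- sub("s$", "", out[i])
  out
}

apply_stemmer <- function(tokens, config) {
  if (identical(config$stemmer, "suffix-s")) stem_suffix_s(tokens) else tokens
}

# ---- layered-document JSONL ----

doc_to_json_line <- function(doc) {
  layers <- lapply(doc$layers, function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(df$value[i], df$start[i], df$length[i])
    })
  })
  relations <- lapply(doc$relations, function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(df$value[i], df$src_start[i], df$src_len[i],
           df$tgt_start[i], df$tgt_len[i])
    })
  })
  obj <- list(doc_id = doc$doc_id, tokens = as.list(doc$tokens),
              layers = layers, relations = relations)
  jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
}

json_line_to_doc <- function(line, lineno) {
  obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("malformed JSON on line %d: %s", lineno,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (is.null(obj$doc_id)) {
    stop(sprintf("line %d: missing doc_id", lineno), call. = FALSE)
  }
  tokens <- vapply(obj$tokens, as.character, character(1))
  layers <- lapply(obj$layers, function(items) {
    if (length(items) == 0L) return(empty_artifact_frame())
    data.frame(
      value = vapply(items, function(t) as.character(t[[1]]), character(1)),
      start = vapply(items, function(t) as.integer(t[[2]]), integer(1)),
      length = vapply(items, function(t) as.integer(t[[3]]), integer(1)),
      stringsAsFactors = FALSE
    )
  })
  relations <- lapply(obj$relations, function(items) {
    if (length(items) == 0L) return(empty_relation_frame())
    data.frame(
      value = vapply(items, function(t) as.character(t[[1]]), character(1)),
      src_start = vapply(items, function(t) as.integer(t[[2]]), integer(1)),
      src_len = vapply(items, function(t) as.integer(t[[3]]), integer(1)),
      tgt_start = vapply(items, function(t) as.integer(t[[4]]), integer(1)),
      tgt_len = vapply(items, function(t) as.integer(t[[5]]), integer(1)),
      stringsAsFactors = FALSE
    )
  })
  layered_document(obj$doc_id, tokens, layers = layers, relations = relations)
}

#' Read layered documents from a JSONL file
#'
#' One document per line:
#' `{"doc_id": str, "tokens": [str, ...],`
#' `"layers": {name: [[value, start, length], ...]},`
#' `"relations": {name: [[value, src_start, src_len, tgt_start, tgt_len], ...]}}`.
#' Every document is validated; any violation rejects the whole file.
#'
#' @param path Path to a JSONL file.
#' @return List of `layered_document` objects.
#' @export
read_layered_jsonl <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    doc <- json_line_to_doc(lines[i], i)
    bad <- validate_document(doc)
    if (length(bad)) {
      stop(sprintf("document %s (line %d) is invalid: %s", doc$doc_id, i,
                   bad[1]), call. = FALSE)
    }
    docs[[i]] <- doc
  }
  docs
}

#' Write layered documents to a JSONL file
#'
#' @param docs List of `layered_document` objects; all must validate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layered_jsonl <- function(docs, path) {
  for (doc in docs) {
    bad <- validate_document(doc)
    if (length(bad)) {
      stop(sprintf("refusing to write invalid document %s: %s", doc$doc_id,
                   bad[1]))
    }
  }
  lines <- vapply(docs, doc_to_json_line, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- TREC-style evaluation files ----

#' Read a TREC qrels file
#'
#' Whitespace-separated lines `topic 0 doc_id grade`. Grades are integers
#' >= 0; grade >= 1 means relevant.
#'
#' @param path Path to the qrels file.
#' @return A data.frame with columns `topic`, `doc_id`, `grade`.
#' @export
read_qrels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(topic = character(), doc_id = character(),
                      grade = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 4L) {
      stop(sprintf("qrels line %d: expected 4 fields, got %d", i,
                   length(parts[[i]])))
    }
    g <- suppressWarnings(as.integer(parts[[i]][4]))
    if (is.na(g) || g < 0L) {
      stop(sprintf("qrels line %d: grade must be an integer >= 0", i))
    }
  }
  qrels <- data.frame(
    topic = vapply(parts, `[`, character(1), 1L),
    doc_id = vapply(parts, `[`, character(1), 3L),
    grade = vapply(parts, function(p) as.integer(p[4]), integer(1)),
    stringsAsFactors = FALSE
  )
  key <- paste(qrels$topic, qrels$doc_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate (topic, doc) judgment: %s", dup))
  }
  qrels
}

#' Write a TREC qrels file
#'
#' @param qrels Data.frame with columns `topic`, `doc_id`, `grade`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(qrels, path) {
  writeLines(sprintf("%s 0 %s %d", qrels$topic, qrels$doc_id,
                     as.integer(qrels$grade)), path)
  invisible(path)
}

#' Write ranked results as a TREC run file
#'
#' Lines `topic Q0 doc_id rank score tag`, sorted by topic then descending
#' score, with the rank field consistent with that order.
#'
#' @param results Named list: topic id -> data.frame with columns `doc_id`
#'   and `score` (a ranking, best first), as returned by [rank_documents()].
#' @param path Output path.
#' @param tag Run tag string recorded in the last column.
#' @return `path`, invisibly.
#' @export
write_run <- function(results, path, tag = "layerlm") {
  lines <- character()
  for (topic in names(results)) {
    df <- results[[topic]]
    if (!nrow(df)) next
    ord <- order(-df$score, df$doc_id)
    df <- df[ord, , drop = FALSE]
    lines <- c(lines, sprintf("%s Q0 %s %d %.9g %s", topic, df$doc_id,
                              seq_len(nrow(df)), df$score, tag))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TREC run file
#'
#' @param path Path to the run file.
#' @return Data.frame with columns `topic`, `doc_id`, `rank`, `score`,
#'   `tag`, ordered by topic then rank.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(topic = character(), doc_id = character(),
                      rank = integer(), score = numeric(), tag = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 6L) {
      stop(sprintf("run line %d: expected 6 fields, got %d", i,
                   length(parts[[i]])))
    }
  }
  run <- data.frame(
    topic = vapply(parts, `[`, character(1), 1L),
    doc_id = vapply(parts, `[`, character(1), 3L),
    rank = vapply(parts, function(p) as.integer(p[4]), integer(1)),
    score = vapply(parts, function(p) as.numeric(p[5]), numeric(1)),
    tag = vapply(parts, `[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
  run[order(run$topic, run$rank), , drop = FALSE]
}

#' Read a topics file (TSV)
#'
#' Lines `topic_id <TAB> text`. Topic ids must be unique.
#'
#' @param path Path to the topics file.
#' @return Data.frame with columns `topic_id`, `text`.
#' @export
read_topics <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(topic_id = character(), text = character(),
                      stringsAsFactors = FALSE))
  }
  m <- regexpr("\t", lines, fixed = TRUE)
  if (any(m < 0L)) {
    stop(sprintf("topics line %d: expected 'topic_id<TAB>text'",
                 which(m < 0L)[1]))
  }
  topics <- data.frame(
    topic_id = substr(lines, 1L, m - 1L),
    text = substring(lines, m + 1L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(topics$topic_id)) {
    stop(sprintf("duplicate topic id: %s",
                 topics$topic_id[duplicated(topics$topic_id)][1]))
  }
  topics
}

#' Write a topics file (TSV)
#'
#' @param topics Data.frame with columns `topic_id`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topics <- function(topics, path) {
  writeLines(paste(topics$topic_id, topics$text, sep = "\t"), path)
  invisible(path)
}
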