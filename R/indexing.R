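# Per-layer positional inverted index with span payloads.
#
# Each layer becomes a LayerIndex: postings (value -> doc -> span table),
# per-document layer sizes |D|_a, the collection layer size |D|_a summed
# over documents, and collection frequencies #t_C. Relation layers
# additionally keep the full per-document relation table so relation
# queries can scan a document's edges. Collection-level phrase and
# relation-match counts are NOT precomputed: the phrase vocabulary is
# unbounded, so they are evaluated lazily at query time and memoized in
# `index$cache` (an environment, shared by reference).

new_layer_accumulator <- function(type) {
  list(type = type, postings = new.env(parent = emptyenv()),
       doc_sizes = new.env(parent = emptyenv()),
       doc_relations = new.env(parent = emptyenv()))
}

add_artifact_postings <- function(acc, df, doc_id) {
  for (v in unique(df$value)) {
    rows <- df[df$value == v, c("start", "length"), drop = FALSE]
    rows <- rows[order(rows$start, rows$length), , drop = FALSE]
    row.names(rows) <- NULL
    plist <- if (exists(v, envir = acc$postings, inherits = FALSE)) {
      get(v, envir = acc$postings)
    } else list()
    plist[[doc_id]] <- rows
    assign(v, plist, envir = acc$postings)
  }
}

add_relation_postings <- function(acc, df, doc_id) {
  df <- df[order(df$src_start, df$src_len, df$tgt_start, df$tgt_len), ,
           drop = FALSE]
  row.names(df) <- NULL
  assign(doc_id, df, envir = acc$doc_relations)
  for (v in unique(df$value)) {
    rows <- df[df$value == v, -1L, drop = FALSE]
    row.names(rows) <- NULL
    plist <- if (exists(v, envir = acc$postings, inherits = FALSE)) {
      get(v, envir = acc$postings)
    } else list()
    plist[[doc_id]] <- rows
    assign(v, plist, envir = acc$postings)
  }
}

finalize_layer <- function(acc, doc_ids) {
  postings <- as.list(acc$postings)
  sizes <- numeric(length(doc_ids))
  names(sizes) <- doc_ids
  stored <- as.list(acc$doc_sizes)
  sizes[names(stored)] <- unlist(stored)
  freq <- vapply(postings, function(plist) {
    sum(vapply(plist, nrow, integer(1)))
  }, numeric(1))
  layer <- list(type = acc$type, postings = postings, doc_sizes = sizes,
                collection_size = sum(sizes), collection_freq = freq)
  if (acc$type == "relation") {
    layer$doc_relations <- as.list(acc$doc_relations)
  }
  layer
}

#' Build a per-layer positional index over a layered corpus
#'
#' Indexes the base token sequence as layer `"text"` (each token a
#' length-1 artifact, lowercased when the config says so) and every
#' artifact and relation layer present in any document. Stopwords are
#' indexed like any other token but the stopword set is recorded, so the
#' scorer can expose both an all-token and a stopped view of |D|_text.
#'
#' @param docs List of `layered_document` objects with unique ids.
#' @param config A [tokenizer_config()]; its `lowercase` and `stopwords`
#'   settings are applied to the text layer.
#' @return A `collection_index` object.
#' @export
build_index <- function(docs, config = tokenizer_config()) {
  doc_ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(doc_ids)) {
    stop(sprintf("duplicate doc_id: %s", doc_ids[duplicated(doc_ids)][1]))
  }
  accs <- list(text = new_layer_accumulator("artifact"))
  get_acc <- function(name, type) {
    if (is.null(accs[[name]])) accs[[name]] <<- new_layer_accumulator(type)
    if (!identical(accs[[name]]$type, type)) {
      stop(sprintf("layer \"%s\" is both an artifact and a relation layer",
                   name))
    }
    accs[[name]]
  }
  stopped_sizes <- numeric(length(doc_ids))
  names(stopped_sizes) <- doc_ids
  for (doc in docs) {
    tokens <- doc$tokens
    if (config$lowercase) tokens <- tolower(tokens)
    acc <- accs$text
    if (length(tokens)) {
      tdf <- data.frame(value = tokens,
                        start = seq_along(tokens) - 1L,
                        length = 1L, stringsAsFactors = FALSE)
      add_artifact_postings(acc, tdf, doc$doc_id)
    }
    assign(doc$doc_id, length(tokens), envir = acc$doc_sizes)
    stopped_sizes[doc$doc_id] <-
      sum(!(tokens %in% config$stopwords))
    for (lname in names(doc$layers)) {
      acc <- get_acc(lname, "artifact")
      df <- doc$layers[[lname]]
      if (nrow(df)) add_artifact_postings(acc, df, doc$doc_id)
      assign(doc$doc_id, nrow(df), envir = acc$doc_sizes)
    }
    for (lname in names(doc$relations)) {
      acc <- get_acc(lname, "relation")
      df <- doc$relations[[lname]]
      if (nrow(df)) add_relation_postings(acc, df, doc$doc_id)
      assign(doc$doc_id, nrow(df), envir = acc$doc_sizes)
    }
  }
  layers <- lapply(accs, finalize_layer, doc_ids = doc_ids)
  idx <- structure(list(
    format_version = 1L,
    doc_ids = doc_ids,
    n_docs = length(doc_ids),
    config = config,
    layers = layers,
    text_doc_sizes_stopped = stopped_sizes,
    cache = new.env(parent = emptyenv())
  ), class = "collection_index")
  idx
}

#' @export
print.collection_index <- function(x, ...) {
  cat(sprintf("<collection_index: %d documents, layers: %s>\n", x$n_docs,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

get_layer <- function(index, layer) {
  li <- index$layers[[layer]]
  if (is.null(li)) stop(sprintf("layer \"%s\" is not indexed", layer))
  li
}

# Spans of artifacts with this exact value in this document (possibly
# empty). Text-layer values are folded to the index's case convention.
artifact_spans <- function(index, layer, value, doc_id) {
  li <- get_layer(index, layer)
  if (li$type != "artifact") {
    stop(sprintf("layer \"%s\" is a relation layer", layer))
  }
  if (identical(layer, "text") && index$config$lowercase) {
    value <- tolower(value)
  }
  plist <- li$postings[[value]]
  if (is.null(plist)) return(empty_artifact_frame()[, c("start", "length")])
  rows <- plist[[doc_id]]
  if (is.null(rows)) return(empty_artifact_frame()[, c("start", "length")])
  rows
}

#' Look up a term's occurrences in one document
#'
#' Returns `#t_D` (the occurrence count of `value` in the document's layer)
#' together with the occurrence spans. Absent values give `(0, empty)`.
#'
#' @param index A `collection_index`.
#' @param layer Indexed artifact layer name.
#' @param value Term value.
#' @param doc_id Document id.
#' @return List with `count` (integer) and `spans` (data.frame with
#'   `start`, `length`).
#' @export
term_lookup <- function(index, layer, value, doc_id) {
  spans <- artifact_spans(index, layer, value, doc_id)
  list(count = nrow(spans), spans = spans)
}

#' Look up relations in one document by label pattern
#'
#' @param index A `collection_index`.
#' @param layer Indexed relation layer name.
#' @param doc_id Document id.
#' @param label_pattern Relation label; `"*"` matches all labels, and glob
#'   wildcards (`?`, `*`) are honoured inside longer patterns.
#' @return Data.frame with columns `value`, `src_start`, `src_len`,
#'   `tgt_start`, `tgt_len` (possibly empty).
#' @export
relation_lookup <- function(index, layer, doc_id, label_pattern = "*") {
  li <- get_layer(index, layer)
  if (li$type != "relation") {
    stop(sprintf("layer \"%s\" is not a relation layer", layer))
  }
  df <- li$doc_relations[[doc_id]]
  if (is.null(df)) return(empty_relation_frame())
  if (identical(label_pattern, "*")) return(df)
  if (grepl("[*?]", label_pattern)) {
    keep <- grepl(utils::glob2rx(label_pattern), df$value)
  } else {
    keep <- df$value == label_pattern
  }
  out <- df[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Per-document layer size used in smoothing denominators
#'
#' `|D|_a` as stored at index time. For the text layer, `stopped = TRUE`
#' returns the count excluding stopwords (the default counts all tokens).
#'
#' @param index A `collection_index`.
#' @param layer Layer name.
#' @param doc_id Document id.
#' @param stopped Use the stopped text-layer size?
#' @return Numeric scalar.
#' @export
index_layer_size <- function(index, layer, doc_id, stopped = FALSE) {
  if (stopped && identical(layer, "text")) {
    return(unname(index$text_doc_sizes_stopped[doc_id]))
  }
  li <- get_layer(index, layer)
  unname(li$doc_sizes[doc_id])
}

#' Collection-wide layer size
#'
#' `|C|_a`: the total number of artifacts of a layer across the whole
#' collection (all tokens, for `"text"`, unless `stopped`).
#'
#' @inheritParams index_layer_size
#' @return Numeric scalar.
#' @export
collection_layer_size <- function(index, layer, stopped = FALSE) {
  if (stopped && identical(layer, "text")) {
    return(sum(index$text_doc_sizes_stopped))
  }
  get_layer(index, layer)$collection_size
}

collection_term_freq <- function(index, layer, value) {
  li <- get_layer(index, layer)
  if (identical(layer, "text") && index$config$lowercase) {
    value <- tolower(value)
  }
  f <- li$collection_freq[value]
  if (is.na(f)) 0 else unname(f)
}

# ---- serialization ----

#' Write an index to disk
#'
#' JSON serialization with a format-version header. Lazy phrase-count
#' caches are not persisted; they are rebuilt on demand after loading.
#'
#' @param index A `collection_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  obj <- unclass(index)
  obj$cache <- NULL
  obj$config <- unclass(obj$config)
  json <- jsonlite::serializeJSON(obj)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an index written by [write_index()]
#'
#' @param path Path to a serialized index.
#' @return A `collection_index`.
#' @export
read_index <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  obj <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                         collapse = "\n"))
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported index format version")
  }
  obj$config <- structure(obj$config, class = "tokenizer_config")
  obj$cache <- new.env(parent = emptyenv())
  structure(obj, class = "collection_index")
}
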