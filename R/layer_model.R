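# Token-aligned layered document representation.
#
# A document is a base sequence of tokens (layer "text") plus any number of
# named artifact layers and relation layers. Every annotation records where
# it sits in the base layer as a span: a 0-based start index and a length in
# tokens. Relation layers record two spans (source and target) per item, so
# a dependency edge survives as pure geometry even though the head/dependent
# artifacts themselves are not referenced (the representation is deliberately
# slightly lossy in that respect).

#' Create a span over base-layer tokens
#'
#' A span locates an annotation in the base token sequence: `start` is the
#' 0-based index of its first token and `length` the number of tokens it
#' covers. The exclusive end index is `start + length`.
#'
#' @param start Integer >= 0, 0-based index of the first covered token.
#' @param length Integer >= 1, number of covered tokens.
#' @return A `layer_span` object (list with `start`, `length`).
#' @examples
#' span(2, 2) # covers base tokens 2 and 3
#' @export
span <- function(start, length) {
  start <- as.integer(start)
  length <- as.integer(length)
  if (is.na(start) || start < 0L) stop("span start must be an integer >= 0")
  if (is.na(length) || length < 1L) stop("span length must be an integer >= 1")
  structure(list(start = start, length = length), class = "layer_span")
}

#' @export
format.layer_span <- function(x, ...) sprintf("(%d,%d)", x$start, x$length)

#' @export
print.layer_span <- function(x, ...) {
  cat("span", format(x), "\n")
  invisible(x)
}

span_end <- function(start, length) start + length

#' Create an artifact (one item of an annotation layer)
#'
#' @param value Non-empty string: the annotation value, e.g. a concept
#'   identifier (`"C0151526"`), a POS tag (`"NN"`), or a lemma.
#' @param start,length Span of the artifact over base-layer tokens.
#' @return A `layer_artifact` object.
#' @export
artifact <- function(value, start, length = 1L) {
  if (!is.character(value) || length(value) != 1L || is.na(value) ||
      !nzchar(value)) {
    stop("artifact value must be a non-empty string")
  }
  sp <- span(start, length)
  structure(list(value = value, span = sp), class = "layer_artifact")
}

#' Create a relation artifact (an edge between two spans)
#'
#' Relation layers hold labelled edges between two base-layer spans, e.g. a
#' dependency-parse arc from a head token (source) to a dependent token
#' (target). The base position of a relation is its target span.
#'
#' @param value Non-empty relation label, e.g. `"nsubj"`.
#' @param source,target `layer_span` objects (or lists coercible via
#'   [span()]), the two endpoints.
#' @return A `relation_artifact` object.
#' @export
relation_artifact <- function(value, source, target) {
  if (!is.character(value) || length(value) != 1L || is.na(value) ||
      !nzchar(value)) {
    stop("relation value must be a non-empty string")
  }
  as_span <- function(x) {
    if (inherits(x, "layer_span")) x else span(x[[1]], x[[2]])
  }
  structure(list(value = value, source = as_span(source),
                 target = as_span(target)),
            class = "relation_artifact")
}

# Internal tabular form: artifact layers are data.frames
# (value, start, length); relation layers are data.frames
# (value, src_start, src_len, tgt_start, tgt_len). Constructors accept
# either data.frames in that shape or lists of artifact()/relation_artifact()
# objects and normalize to the tabular form, which everything downstream
# (indexing, scoring, IO) consumes.

empty_artifact_frame <- function() {
  data.frame(value = character(), start = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

empty_relation_frame <- function() {
  data.frame(value = character(), src_start = integer(), src_len = integer(),
             tgt_start = integer(), tgt_len = integer(),
             stringsAsFactors = FALSE)
}

as_artifact_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("value", "start", "length") %in% names(x)))
    df <- data.frame(value = as.character(x$value),
                     start = as.integer(x$start),
                     length = as.integer(x$length),
                     stringsAsFactors = FALSE)
    return(df)
  }
  if (length(x) == 0L) return(empty_artifact_frame())
  data.frame(
    value = vapply(x, function(a) a$value, character(1)),
    start = vapply(x, function(a) a$span$start, integer(1)),
    length = vapply(x, function(a) a$span$length, integer(1)),
    stringsAsFactors = FALSE
  )
}

as_relation_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("value", "src_start", "src_len", "tgt_start",
                    "tgt_len") %in% names(x)))
    return(data.frame(value = as.character(x$value),
                      src_start = as.integer(x$src_start),
                      src_len = as.integer(x$src_len),
                      tgt_start = as.integer(x$tgt_start),
                      tgt_len = as.integer(x$tgt_len),
                      stringsAsFactors = FALSE))
  }
  if (length(x) == 0L) return(empty_relation_frame())
  data.frame(
    value = vapply(x, function(r) r$value, character(1)),
    src_start = vapply(x, function(r) r$source$start, integer(1)),
    src_len = vapply(x, function(r) r$source$length, integer(1)),
    tgt_start = vapply(x, function(r) r$target$start, integer(1)),
    tgt_len = vapply(x, function(r) r$target$length, integer(1)),
    stringsAsFactors = FALSE
  )
}

sort_artifact_frame <- function(df) {
  df <- df[order(df$start, df$length), , drop = FALSE]
  row.names(df) <- NULL
  df
}

#' Create a layered document
#'
#' Bundles a base token sequence with named artifact layers (e.g. `cui`,
#' `tui`, `lemma`, `pos`) and relation layers (e.g. `dep`). Artifact layers
#' are stored sorted by `(start, length)`. The layer name `"text"` is
#' reserved for the base layer itself.
#'
#' @param doc_id Document identifier string.
#' @param tokens Character vector of base-layer tokens.
#' @param layers Named list; each element either a data.frame with columns
#'   `value`, `start`, `length` or a list of [artifact()] objects.
#' @param relations Named list; each element either a data.frame with columns
#'   `value`, `src_start`, `src_len`, `tgt_start`, `tgt_len` or a list of
#'   [relation_artifact()] objects.
#' @return A `layered_document` object.
#' @seealso [validate_document()], [layer_size()]
#' @export
layered_document <- function(doc_id, tokens, layers = list(),
                             relations = list()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  tokens <- as.character(tokens)
  layers <- lapply(layers, function(x) sort_artifact_frame(as_artifact_frame(x)))
  relations <- lapply(relations, as_relation_frame)
  if (length(layers) && is.null(names(layers))) stop("layers must be named")
  if (length(relations) && is.null(names(relations))) {
    stop("relation layers must be named")
  }
  structure(list(doc_id = doc_id, tokens = tokens, layers = layers,
                 relations = relations),
            class = "layered_document")
}

#' @export
print.layered_document <- function(x, ...) {
  cat(sprintf("<layered_document %s: %d tokens, %d artifact layer(s), %d relation layer(s)>\n",
              x$doc_id, length(x$tokens), length(x$layers),
              length(x$relations)))
  invisible(x)
}

#' Validate a layered document's integrity rules
#'
#' Checks every invariant of the layered representation and reports
#' violations instead of raising: span bounds against the token count,
#' non-empty values, positive lengths, sortedness of artifact layers, and
#' disjointness of artifact vs relation layer names (with `"text"` reserved).
#'
#' @param doc A `layered_document`.
#' @return Character vector of human-readable violation descriptions; empty
#'   when the document is valid.
#' @examples
#' d <- layered_document("d1", c("pregnancy", "with", "preterm", "delivery"),
#'                       layers = list(cui = list(artifact("C0151526", 2, 2))))
#' validate_document(d) # character(0)
#' @export
validate_document <- function(doc) {
  bad <- character()
  n <- length(doc$tokens)
  if (any(is.na(doc$tokens))) bad <- c(bad, "layer text: NA token present")
  check_span <- function(where, i, start, len) {
    out <- character()
    if (is.na(start) || start < 0L) {
      out <- c(out, sprintf("%s item %d: span start %s < 0", where, i, start))
    }
    if (is.na(len) || len < 1L) {
      out <- c(out, sprintf("%s item %d: span length %s < 1", where, i, len))
    }
    if (!is.na(start) && !is.na(len) && start + len > n) {
      out <- c(out, sprintf("%s item %d: span end %d exceeds token count %d",
                            where, i, start + len, n))
    }
    out
  }
  if ("text" %in% names(doc$layers) || "text" %in% names(doc$relations)) {
    bad <- c(bad, "layer name \"text\" is reserved for the base layer")
  }
  shared <- intersect(names(doc$layers), names(doc$relations))
  if (length(shared)) {
    bad <- c(bad, sprintf("layer name(s) %s used for both artifacts and relations",
                          paste(shared, collapse = ", ")))
  }
  for (lname in names(doc$layers)) {
    df <- doc$layers[[lname]]
    where <- sprintf("layer %s", lname)
    if (nrow(df) == 0L) next
    if (any(!nzchar(df$value) | is.na(df$value))) {
      bad <- c(bad, sprintf("%s: empty artifact value", where))
    }
    for (i in seq_len(nrow(df))) {
      bad <- c(bad, check_span(where, i, df$start[i], df$length[i]))
    }
    if (is.unsorted(order(df$start, df$length))) {
      bad <- c(bad, sprintf("%s: artifacts not sorted by (start, length)", where))
    }
  }
  for (lname in names(doc$relations)) {
    df <- doc$relations[[lname]]
    where <- sprintf("relation layer %s", lname)
    if (nrow(df) == 0L) next
    if (any(!nzchar(df$value) | is.na(df$value))) {
      bad <- c(bad, sprintf("%s: empty relation label", where))
    }
    for (i in seq_len(nrow(df))) {
      bad <- c(bad, check_span(sprintf("%s (source)", where), i,
                               df$src_start[i], df$src_len[i]))
      bad <- c(bad, check_span(sprintf("%s (target)", where), i,
                               df$tgt_start[i], df$tgt_len[i]))
    }
  }
  bad
}

#' Number of artifacts a document carries in a layer
#'
#' `|D|_a` in the scoring model: the count of artifacts in layer `a` of
#' document `D`. For the base layer (`"text"`) this is the token count; for
#' relation layers, the number of relation artifacts.
#'
#' @param doc A `layered_document`.
#' @param layer Layer name; `"text"` selects the base layer.
#' @return Non-negative integer.
#' @export
layer_size <- function(doc, layer) {
  if (identical(layer, "text")) return(length(doc$tokens))
  if (layer %in% names(doc$layers)) return(nrow(doc$layers[[layer]]))
  if (layer %in% names(doc$relations)) return(nrow(doc$relations[[layer]]))
  stop(sprintf("layer \"%s\" is not present in document %s", layer,
               doc$doc_id))
}
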