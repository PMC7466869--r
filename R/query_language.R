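# The aligned-layer query language.
#
# Grammar (whitespace separates top-level nodes; any node may carry a
# trailing "^w" weight, w > 0):
#
#   term      := value | layer:value              (bare value -> layer "text")
#   list      := #l(member|member|...)            members are terms
#   phrase    := #p(w|o|c1|c2|...)                w >= 1 window in base tokens,
#                                                 o in {true,false}, components
#                                                 are terms or lists, >= 2
#   relation  := #r(layer|SRC|TGT)                SRC/TGT a term or "*"
#
# Rendering then re-parsing is the identity on valid ASTs.

new_node <- function(type, fields, weight = 1) {
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight <= 0) {
    stop("node weight must be a positive number")
  }
  structure(c(list(type = type), fields, list(weight = as.numeric(weight))),
            class = "query_node")
}

#' Query node constructors
#'
#' Build query AST nodes directly (the usual entry point is
#' [parse_query()]). `term_node` addresses a single value in one layer;
#' `list_node` groups terms scored individually (and usable as a
#' disjunctive phrase component); `phrase_node` is a cross-layer windowed
#' phrase; `relation_node` matches labelled edges whose endpoints overlap
#' artifacts matching the source/target patterns.
#'
#' @param layer Layer name (`"text"` for the base layer).
#' @param value Term value.
#' @param weight Positive node weight (default 1).
#' @return A `query_node`.
#' @export
term_node <- function(layer, value, weight = 1) {
  stopifnot(nzchar(layer), nzchar(value))
  new_node("term", list(layer = layer, value = value), weight)
}

#' @rdname term_node
#' @param members List of term nodes.
#' @export
list_node <- function(members, weight = 1) {
  if (!length(members)) stop("list query needs at least one member")
  ok <- vapply(members, function(m) {
    inherits(m, "query_node") && m$type == "term"
  }, logical(1))
  if (!all(ok)) stop("list members must be term nodes")
  new_node("list", list(members = members), weight)
}

#' @rdname term_node
#' @param window Window size in base-layer tokens (integer >= 1).
#' @param ordered Logical: must components appear in query order,
#'   non-overlapping and sequential?
#' @param components List of >= 2 term or list nodes.
#' @export
phrase_node <- function(window, ordered, components, weight = 1) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("phrase window must be >= 1")
  if (length(components) < 2L) stop("phrase needs at least 2 components")
  ok <- vapply(components, function(m) {
    inherits(m, "query_node") && m$type %in% c("term", "list")
  }, logical(1))
  if (!all(ok)) stop("phrase components must be term or list nodes")
  new_node("phrase", list(window = window, ordered = isTRUE(ordered),
                          components = components), weight)
}

#' @rdname term_node
#' @param label Relation label pattern; `"*"` matches any label.
#' @param source,target A term node, or `"*"` to match unconditionally.
#' @export
relation_node <- function(layer, label, source = "*", target = "*",
                          weight = 1) {
  stopifnot(nzchar(layer), nzchar(label))
  chk <- function(x, what) {
    if (identical(x, "*")) return(x)
    if (inherits(x, "query_node") && x$type == "term") return(x)
    stop(sprintf("relation %s pattern must be a term node or \"*\"", what))
  }
  new_node("relation", list(layer = layer, label = label,
                            source = chk(source, "source"),
                            target = chk(target, "target")), weight)
}

new_query <- function(nodes) {
  structure(list(nodes = nodes), class = "layer_query")
}

#' @export
print.layer_query <- function(x, ...) {
  cat(render_query(x), "\n")
  invisible(x)
}

#' @export
print.query_node <- function(x, ...) {
  cat(render_node(x), "\n")
  invisible(x)
}

# ---- parser ----

new_cursor <- function(text) {
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(text, "")[[1]]
  env$pos <- 1L
  env$n <- length(env$chars)
  env
}

cur_eof <- function(cu) cu$pos > cu$n
cur_peek <- function(cu) if (cur_eof(cu)) "" else cu$chars[cu$pos]
cur_skip_ws <- function(cu) {
  while (!cur_eof(cu) && grepl("^\\s$", cu$chars[cu$pos])) {
    cu$pos <- cu$pos + 1L
  }
}
cur_expect <- function(cu, ch) {
  if (cur_peek(cu) != ch) {
    stop(sprintf("parse error at position %d: expected \"%s\", found \"%s\"",
                 cu$pos, ch, cur_peek(cu)), call. = FALSE)
  }
  cu$pos <- cu$pos + 1L
}
cur_ahead <- function(cu, s) {
  k <- nchar(s)
  if (cu$pos + k - 1L > cu$n) return(FALSE)
  paste(cu$chars[cu$pos:(cu$pos + k - 1L)], collapse = "") == s
}

# Read a raw token up to any of the stop characters (always stopping at
# "^", "(", ")", "|", and whitespace).
cur_token <- function(cu) {
  stops <- c("^", "(", ")", "|")
  out <- character()
  while (!cur_eof(cu)) {
    ch <- cu$chars[cu$pos]
    if (ch %in% stops || grepl("^\\s$", ch)) break
    out <- c(out, ch)
    cu$pos <- cu$pos + 1L
  }
  paste(out, collapse = "")
}

parse_weight_suffix <- function(cu) {
  if (cur_peek(cu) != "^") return(1)
  cu$pos <- cu$pos + 1L
  at <- cu$pos
  tok <- cur_token(cu)
  w <- suppressWarnings(as.numeric(tok))
  if (!nzchar(tok) || is.na(w) || w <= 0) {
    stop(sprintf("parse error at position %d: weight must be a positive number",
                 at), call. = FALSE)
  }
  w
}

parse_term_at <- function(cu) {
  at <- cu$pos
  tok <- cur_token(cu)
  if (!nzchar(tok)) {
    stop(sprintf("parse error at position %d: expected a term", at),
         call. = FALSE)
  }
  colon <- regexpr(":", tok, fixed = TRUE)
  if (colon > 0L) {
    layer <- substr(tok, 1L, colon - 1L)
    value <- substring(tok, colon + 1L)
    if (!nzchar(layer) || !nzchar(value)) {
      stop(sprintf("parse error at position %d: malformed layer:value term \"%s\"",
                   at, tok), call. = FALSE)
    }
    term_node(layer, value)
  } else {
    term_node("text", tok)
  }
}

parse_list_at <- function(cu) {
  cu$pos <- cu$pos + 2L # consume "#l"
  cur_expect(cu, "(")
  members <- list()
  repeat {
    cur_skip_ws(cu)
    members <- c(members, list(parse_term_at(cu)))
    cur_skip_ws(cu)
    if (cur_peek(cu) == "|") {
      cu$pos <- cu$pos + 1L
    } else break
  }
  cur_expect(cu, ")")
  list_node(members)
}

parse_phrase_at <- function(cu) {
  at <- cu$pos
  cu$pos <- cu$pos + 2L # consume "#p"
  cur_expect(cu, "(")
  cur_skip_ws(cu)
  wtok <- cur_token(cu)
  w <- suppressWarnings(as.integer(wtok))
  if (is.na(w) || w < 1L) {
    stop(sprintf("parse error at position %d: phrase window must be an integer >= 1",
                 at), call. = FALSE)
  }
  cur_skip_ws(cu); cur_expect(cu, "|"); cur_skip_ws(cu)
  otok <- cur_token(cu)
  if (!otok %in% c("true", "false")) {
    stop(sprintf("parse error at position %d: phrase ordering must be true or false",
                 at), call. = FALSE)
  }
  comps <- list()
  while (cur_peek(cu) == "|") {
    cu$pos <- cu$pos + 1L
    cur_skip_ws(cu)
    comp <- if (cur_ahead(cu, "#l(")) parse_list_at(cu) else parse_term_at(cu)
    comps <- c(comps, list(comp))
    cur_skip_ws(cu)
  }
  cur_expect(cu, ")")
  if (length(comps) < 2L) {
    stop(sprintf("parse error at position %d: phrase needs at least 2 components",
                 at), call. = FALSE)
  }
  phrase_node(w, identical(otok, "true"), comps)
}

parse_relation_at <- function(cu) {
  at <- cu$pos
  cu$pos <- cu$pos + 2L # consume "#r"
  cur_expect(cu, "(")
  cur_skip_ws(cu)
  layer <- cur_token(cu)
  if (!nzchar(layer)) {
    stop(sprintf("parse error at position %d: relation needs a layer", at),
         call. = FALSE)
  }
  colon <- regexpr(":", layer, fixed = TRUE)
  label <- "*"
  if (colon > 0L) {
    label <- substring(layer, colon + 1L)
    layer <- substr(layer, 1L, colon - 1L)
  }
  pat <- function() {
    cur_skip_ws(cu)
    if (cur_ahead(cu, "*")) {
      tok <- cur_token(cu)
      if (!identical(tok, "*")) {
        stop(sprintf("parse error at position %d: malformed pattern \"%s\"",
                     at, tok), call. = FALSE)
      }
      "*"
    } else parse_term_at(cu)
  }
  cur_skip_ws(cu); cur_expect(cu, "|")
  src <- pat()
  cur_skip_ws(cu); cur_expect(cu, "|")
  tgt <- pat()
  cur_skip_ws(cu)
  cur_expect(cu, ")")
  relation_node(layer, label, src, tgt)
}

parse_node_at <- function(cu) {
  node <- if (cur_ahead(cu, "#p(")) {
    parse_phrase_at(cu)
  } else if (cur_ahead(cu, "#l(")) {
    parse_list_at(cu)
  } else if (cur_ahead(cu, "#r(")) {
    parse_relation_at(cu)
  } else if (cur_peek(cu) %in% c(")", "|", "(", "^")) {
    stop(sprintf("parse error at position %d: unexpected \"%s\"", cu$pos,
                 cur_peek(cu)), call. = FALSE)
  } else {
    parse_term_at(cu)
  }
  w <- parse_weight_suffix(cu)
  node$weight <- w
  node
}

#' Parse an aligned-layer query string
#'
#' Accepts the query dialect with `layer:value` terms, `#l(...)` lists,
#' `#p(w|o|...)` phrases, `#r(layer|SRC|TGT)` (optionally
#' `#r(layer:label|SRC|TGT)`) relations, and `^w` weights. Whitespace is
#' tolerated around `|` separators.
#'
#' @param text Query string.
#' @return A `layer_query` (ordered list of weighted `query_node`s).
#' @examples
#' parse_query("cui:C0019196 cui:C0019158")
#' parse_query("#p(8|true|coinfected|hepatitis)^0.1")
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  cu <- new_cursor(text)
  nodes <- list()
  cur_skip_ws(cu)
  while (!cur_eof(cu)) {
    nodes <- c(nodes, list(parse_node_at(cu)))
    cur_skip_ws(cu)
  }
  if (!length(nodes)) stop("parse error: empty query")
  new_query(nodes)
}

# ---- renderer ----

format_weight <- function(w) {
  format(w, digits = 15, scientific = FALSE, trim = TRUE)
}

render_node <- function(node, with_weight = TRUE) {
  body <- switch(node$type,
    term = if (identical(node$layer, "text")) node$value else {
      paste0(node$layer, ":", node$value)
    },
    list = paste0("#l(", paste(vapply(node$members, render_node, character(1),
                                      with_weight = FALSE),
                               collapse = "|"), ")"),
    phrase = paste0("#p(", node$window, "|",
                    if (node$ordered) "true" else "false", "|",
                    paste(vapply(node$components, render_node, character(1),
                                 with_weight = FALSE), collapse = "|"), ")"),
    relation = {
      head <- if (identical(node$label, "*")) node$layer else {
        paste0(node$layer, ":", node$label)
      }
      pat <- function(x) if (identical(x, "*")) "*" else {
        render_node(x, with_weight = FALSE)
      }
      paste0("#r(", head, "|", pat(node$source), "|", pat(node$target), ")")
    },
    stop(sprintf("unknown node type %s", node$type))
  )
  if (with_weight && node$weight != 1) {
    body <- paste0(body, "^", format_weight(node$weight))
  }
  body
}

#' Render a query to its canonical string form
#'
#' `parse_query(render_query(q))` is structurally identical to `q`; default
#' weights (1) are elided.
#'
#' @param q A `layer_query` or single `query_node`.
#' @return A single string in the query dialect.
#' @export
render_query <- function(q) {
  if (inherits(q, "query_node")) return(render_node(q))
  paste(vapply(q$nodes, render_node, character(1)), collapse = " ")
}

# ---- sequential dependence expansion ----

#' Sequential-dependence expansion constants
#'
#' Interpolation weights and window scaling of the Markov-random-field
#' term-dependence expansion: each atom is kept with weight `lambda_term`;
#' every contiguous atom subsequence of length k (2 <= k <=
#' `max_components`) adds an ordered phrase with weight `lambda_ordered`
#' and an unordered phrase with weight `lambda_unordered`, both with
#' window `window_per_component * k` base tokens.
#'
#' @param lambda_term Weight on unigram atoms (default 0.85).
#' @param lambda_ordered Weight on ordered phrases (default 0.1).
#' @param lambda_unordered Weight on unordered phrases (default 0.05).
#' @param window_per_component Window tokens per phrase component
#'   (default 4, giving windows 8/12/16/20 for k = 2..5).
#' @param max_components Cap on phrase length k (default 5).
#' @return An `sdm_config` object.
#' @export
sdm_config <- function(lambda_term = 0.85, lambda_ordered = 0.1,
                       lambda_unordered = 0.05, window_per_component = 4L,
                       max_components = 5L) {
  stopifnot(lambda_term > 0, lambda_ordered > 0, lambda_unordered > 0,
            window_per_component >= 1L, max_components >= 2L)
  structure(list(lambda_term = lambda_term, lambda_ordered = lambda_ordered,
                 lambda_unordered = lambda_unordered,
                 window_per_component = as.integer(window_per_component),
                 max_components = as.integer(max_components)),
            class = "sdm_config")
}

strip_weight <- function(node) {
  node$weight <- 1
  node
}

#' Expand query atoms with the sequential dependence model
#'
#' Takes an ordered sequence of atoms (term or list nodes; lists act as
#' disjunctive phrase components) and emits the atoms weighted by
#' `lambda_term` plus, for every contiguous subsequence of length k from 2
#' up to `max_components`, an ordered and an unordered phrase over that
#' subsequence with window `window_per_component * k`, shortest
#' subsequences first, left to right. With n atoms the result has
#' `n + 2 * sum(n - k + 1, k = 2..min(n, max_components))` nodes.
#'
#' @param atoms A `layer_query`, a list of term/list `query_node`s, or a
#'   query string to parse.
#' @param config An [sdm_config()].
#' @return A `layer_query`.
#' @examples
#' render_query(sdm_expand("cui:C0019196 cui:C0019158"))
#' @export
sdm_expand <- function(atoms, config = sdm_config()) {
  if (is.character(atoms)) atoms <- parse_query(atoms)
  if (inherits(atoms, "layer_query")) atoms <- atoms$nodes
  if (!length(atoms)) stop("sdm_expand needs at least one atom")
  ok <- vapply(atoms, function(a) {
    inherits(a, "query_node") && a$type %in% c("term", "list")
  }, logical(1))
  if (!all(ok)) stop("sdm_expand atoms must be term or list nodes")
  atoms <- lapply(atoms, strip_weight)
  n <- length(atoms)
  nodes <- lapply(atoms, function(a) {
    a$weight <- config$lambda_term
    a
  })
  for (k in 2:min(n, config$max_components)) {
    if (k > n) break
    w <- config$window_per_component * k
    for (i in seq_len(n - k + 1L)) {
      comps <- atoms[i:(i + k - 1L)]
      nodes <- c(nodes,
                 list(phrase_node(w, TRUE, comps, config$lambda_ordered),
                      phrase_node(w, FALSE, comps, config$lambda_unordered)))
    }
  }
  new_query(nodes)
}
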