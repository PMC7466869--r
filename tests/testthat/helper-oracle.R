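# Brute-force oracle: recomputes every count, probability, score, and AP
# by scanning raw layered documents directly. It never touches the
# inverted index or the engine's counting code, so it serves as an
# independent route for equivalence checks. All oracle corpora use
# lowercase tokens and no stopwords.

o_candidates <- function(doc, member) {
  if (member$layer == "text") {
    pos <- which(doc$tokens == member$value) - 1L
    if (!length(pos)) return(NULL)
    return(data.frame(start = pos, end = pos + 1L))
  }
  df <- doc$layers[[member$layer]]
  if (is.null(df)) return(NULL)
  sel <- df[df$value == member$value, , drop = FALSE]
  if (!nrow(sel)) return(NULL)
  data.frame(start = sel$start, end = sel$start + sel$length)
}

o_component_candidates <- function(doc, comp) {
  members <- if (comp$type == "term") list(comp) else comp$members
  keys <- vapply(members, function(m) paste(m$layer, m$value), character(1))
  members <- members[!duplicated(keys)]
  frames <- Filter(Negate(is.null), lapply(members, o_candidates, doc = doc))
  if (!length(frames)) return(NULL)
  do.call(rbind, frames)
}

o_term_count <- function(doc, layer, value) {
  cand <- o_candidates(doc, term_node(layer, value))
  if (is.null(cand)) 0L else nrow(cand)
}

o_layer_size <- function(doc, layer) {
  if (layer == "text") return(length(doc$tokens))
  if (!is.null(doc$layers[[layer]])) return(nrow(doc$layers[[layer]]))
  if (!is.null(doc$relations[[layer]])) return(nrow(doc$relations[[layer]]))
  0L
}

# Full enumeration of all artifact tuples, filtering by the stated window
# semantics: f is the tuple member with minimal start (ties: minimal end);
# every member's start must lie in [f.start, f.end + w]. Ordered tuples
# must additionally be sequential and non-overlapping in component order
# with the last start within w of the first end.
o_phrase_count <- function(doc, comps, w, ordered) {
  cands <- lapply(comps, o_component_candidates, doc = doc)
  if (any(vapply(cands, is.null, logical(1)))) return(0L)
  sizes <- vapply(cands, nrow, integer(1))
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  count <- 0L
  k <- length(comps)
  for (g in seq_len(nrow(grid))) {
    starts <- vapply(seq_len(k), function(i) cands[[i]]$start[grid[g, i]],
                     numeric(1))
    ends <- vapply(seq_len(k), function(i) cands[[i]]$end[grid[g, i]],
                   numeric(1))
    f <- order(starts, ends)[1]
    if (any(starts > ends[f] + w)) next
    if (ordered) {
      if (any(starts[-1] < ends[-k])) next
      if (starts[k] - ends[1] > w) next
    }
    count <- count + 1L
  }
  count
}

o_relation_count <- function(doc, rel) {
  rels <- doc$relations[[rel$layer]]
  if (is.null(rels) || !nrow(rels)) return(0L)
  if (!identical(rel$label, "*")) {
    rels <- rels[rels$value == rel$label, , drop = FALSE]
  }
  if (!nrow(rels)) return(0L)
  overlaps <- function(pattern, start, end) {
    if (identical(pattern, "*")) return(TRUE)
    cand <- o_candidates(doc, pattern)
    if (is.null(cand)) return(FALSE)
    any(pmax(cand$start, start) < pmin(cand$end, end))
  }
  n <- 0L
  for (i in seq_len(nrow(rels))) {
    if (overlaps(rel$source, rels$src_start[i],
                 rels$src_start[i] + rels$src_len[i]) &&
        overlaps(rel$target, rels$tgt_start[i],
                 rels$tgt_start[i] + rels$tgt_len[i])) {
      n <- n + 1L
    }
  }
  n
}

o_dirichlet <- function(t_d, t_c, d_size, c_size, mu) {
  if (c_size == 0 || t_c == 0) return(0)
  (t_d + mu * t_c / c_size) / (d_size + mu)
}

o_score_term <- function(docs, term, doc_id, mu) {
  doc <- docs[[which(vapply(docs, `[[`, character(1), "doc_id") == doc_id)]]
  t_c <- sum(vapply(docs, o_term_count, integer(1), layer = term$layer,
                    value = term$value))
  c_size <- sum(vapply(docs, o_layer_size, integer(1), layer = term$layer))
  o_dirichlet(o_term_count(doc, term$layer, term$value), t_c,
              o_layer_size(doc, term$layer), c_size, mu)
}

o_score_phrase <- function(docs, phrase, doc_id, mu) {
  doc <- docs[[which(vapply(docs, `[[`, character(1), "doc_id") == doc_id)]]
  layers <- unique(unlist(lapply(phrase$components, function(comp) {
    members <- if (comp$type == "term") list(comp) else comp$members
    vapply(members, `[[`, character(1), "layer")
  })))
  ph_d <- o_phrase_count(doc, phrase$components, phrase$window,
                         phrase$ordered)
  ph_c <- sum(vapply(docs, o_phrase_count, integer(1),
                     comps = phrase$components, w = phrase$window,
                     ordered = phrase$ordered))
  d_size <- max(vapply(layers, o_layer_size, integer(1), doc = doc))
  c_size <- max(vapply(layers, function(l) {
    sum(vapply(docs, o_layer_size, integer(1), layer = l))
  }, numeric(1)))
  o_dirichlet(ph_d, ph_c, d_size, c_size, mu)
}

o_score_relation <- function(docs, rel, doc_id, mu) {
  doc <- docs[[which(vapply(docs, `[[`, character(1), "doc_id") == doc_id)]]
  t_c <- sum(vapply(docs, o_relation_count, integer(1), rel = rel))
  c_size <- sum(vapply(docs, o_layer_size, integer(1), layer = rel$layer))
  o_dirichlet(o_relation_count(doc, rel), t_c,
              o_layer_size(doc, rel$layer), c_size, mu)
}

o_score_document <- function(docs, q, doc_id, mu) {
  if (is.character(q)) q <- parse_query(q)
  score <- 0
  for (node in q$nodes) {
    units <- if (node$type == "list") {
      lapply(node$members, function(m) { m$weight <- node$weight; m })
    } else list(node)
    for (u in units) {
      p <- switch(u$type,
                  term = o_score_term(docs, u, doc_id, mu),
                  phrase = o_score_phrase(docs, u, doc_id, mu),
                  relation = o_score_relation(docs, u, doc_id, mu))
      if (p > 0) score <- score + u$weight * log(p)
    }
  }
  score
}

o_rank <- function(docs, q, mu) {
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  scores <- vapply(ids, function(d) o_score_document(docs, q, d, mu),
                   numeric(1))
  ids[order(-scores, ids)]
}

# Loop-based AP, written differently from the package's vectorized form.
o_average_precision <- function(ranked, relevant) {
  r_total <- length(relevant)
  hits <- 0
  s <- 0
  for (i in seq_along(ranked)) {
    if (ranked[i] %in% relevant) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / r_total
}

# Reference bag-of-words Dirichlet query-likelihood scorer over raw text
# tokens only (the classical special case).
ref_ql_scores <- function(docs, query_tokens, mu) {
  token_lists <- lapply(docs, `[[`, "tokens")
  c_size <- sum(lengths(token_lists))
  cf <- table(unlist(token_lists))
  scores <- vapply(token_lists, function(toks) {
    s <- 0
    for (t in query_tokens) {
      t_c <- if (t %in% names(cf)) cf[[t]] else 0
      if (t_c == 0) next
      s <- s + log((sum(toks == t) + mu * t_c / c_size) /
                     (length(toks) + mu))
    }
    s
  }, numeric(1))
  names(scores) <- vapply(docs, `[[`, character(1), "doc_id")
  scores
}
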