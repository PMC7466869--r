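# Aligned-layer scoring: Dirichlet-smoothed per-layer term likelihoods,
# cross-layer windowed phrase likelihoods, list and relation operators,
# and their weighted log-linear combination for ranked retrieval.
#
# Term probability (query-likelihood with Dirichlet smoothing, evaluated
# entirely within the term's own layer a):
#
#   P(t | D) = (#t_D + mu * #t_C / |C|_a) / (|D|_a + mu)
#
# where #t_D / #t_C are document / collection occurrence counts and
# |D|_a / |C|_a document / collection layer sizes. Phrase probability uses
# the same shape with phrase-match counts and, since a phrase may stipulate
# several layers, the size of the LARGEST stipulated layer in both
# denominator positions (a backed-off, non-sparse estimate; the product of
# layer sizes is available behind `phrase_denominator = "product"` but is
# not the default).

#' Dirichlet smoothing configuration
#'
#' @param mu Dirichlet pseudo-count, > 0. Default 2000, the conventional
#'   query-likelihood setting.
#' @param per_layer Named list of per-layer `mu` overrides.
#' @param use_stopped_text_sizes If `TRUE`, |D|_text excludes stopwords.
#'   Default `FALSE`: all stored tokens count.
#' @param drop_stopword_terms Drop text-layer query terms that are
#'   stopwords of the index's tokenizer config (query-side stopping,
#'   symmetric with indexing). Default `TRUE`.
#' @param phrase_denominator `"max"` (default; largest stipulated layer) or
#'   `"product"` (product of stipulated layer sizes).
#' @param verbose Emit messages when zero-evidence query nodes are skipped.
#' @return A `smoothing_config` object.
#' @export
smoothing_config <- function(mu = 2000, per_layer = list(),
                             use_stopped_text_sizes = FALSE,
                             drop_stopword_terms = TRUE,
                             phrase_denominator = c("max", "product"),
                             verbose = FALSE) {
  stopifnot(is.numeric(mu), mu > 0)
  if (length(per_layer) && any(unlist(per_layer) <= 0)) {
    stop("all per-layer mu overrides must be > 0")
  }
  structure(list(mu = mu, per_layer = per_layer,
                 use_stopped_text_sizes = isTRUE(use_stopped_text_sizes),
                 drop_stopword_terms = isTRUE(drop_stopword_terms),
                 phrase_denominator = match.arg(phrase_denominator),
                 verbose = isTRUE(verbose)),
            class = "smoothing_config")
}

mu_for <- function(cfg, layer) {
  ov <- cfg$per_layer[[layer]]
  if (is.null(ov)) cfg$mu else ov
}

#' Score a single term query against one document
#'
#' Dirichlet-smoothed probability of the term under the document's
#' language model for the term's layer. Returns 0 when the term has no
#' collection evidence (out-of-collection value), and 0 with a warning
#' when the layer is empty collection-wide.
#'
#' @param index A `collection_index`.
#' @param term A term `query_node` (see [term_node()]).
#' @param doc_id Document id.
#' @param cfg A [smoothing_config()].
#' @return Probability in `[0, 1]`.
#' @export
score_term <- function(index, term, doc_id, cfg = smoothing_config()) {
  stopifnot(inherits(term, "query_node"), term$type == "term")
  layer <- term$layer
  mu <- mu_for(cfg, layer)
  stopped <- cfg$use_stopped_text_sizes
  coll_size <- collection_layer_size(index, layer, stopped = stopped)
  if (coll_size == 0) {
    warning(sprintf("layer \"%s\" is empty collection-wide; scoring 0", layer))
    return(0)
  }
  t_c <- collection_term_freq(index, layer, term$value)
  if (t_c == 0) return(0)
  t_d <- term_lookup(index, layer, term$value, doc_id)$count
  d_size <- index_layer_size(index, layer, doc_id, stopped = stopped)
  (t_d + mu * t_c / coll_size) / (d_size + mu)
}

# ---- phrase matching ----

# Candidate artifacts for one phrase component in one document:
# data.frame(start, end) with one row per matching artifact. A term
# matches its own postings; a list matches the union of its (deduplicated)
# members' postings.
component_candidates <- function(index, comp, doc_id) {
  members <- if (comp$type == "term") list(comp) else comp$members
  keys <- vapply(members, function(m) paste0(m$layer, "\r", m$value),
                 character(1))
  members <- members[!duplicated(keys)]
  frames <- lapply(members, function(m) {
    sp <- artifact_spans(index, m$layer, m$value, doc_id)
    data.frame(start = sp$start, end = sp$start + sp$length)
  })
  do.call(rbind, frames)
}

component_layers <- function(comp) {
  members <- if (comp$type == "term") list(comp) else comp$members
  vapply(members, function(m) m$layer, character(1))
}

# Ordered tuples: components in query order, each next artifact starting at
# or after the previous one ends (non-overlapping, sequential), and the last
# artifact starting within `window` tokens of the first artifact's end.
count_ordered_tuples <- function(cands, window) {
  k <- length(cands)
  recurse <- function(i, prev_end, first_end) {
    df <- cands[[i]]
    ok <- df$start >= prev_end & df$start <= first_end + window
    if (i == k) return(sum(ok))
    total <- 0L
    for (j in which(ok)) {
      total <- total + recurse(i + 1L, df$end[j], first_end)
    }
    total
  }
  first <- cands[[1L]]
  total <- 0L
  for (j in seq_len(nrow(first))) {
    total <- total + recurse(2L, first$end[j], first$end[j])
  }
  total
}

# Unordered tuples: let f be the tuple member with minimal start (ties:
# minimal end); every member's start must lie within [f.start, f.end +
# window]. Members may come from any component in any order, and the same
# artifact may fill several slots. Counted by conditioning on which slot
# holds the (tie-broken) earliest artifact.
count_unordered_tuples <- function(cands, window) {
  k <- length(cands)
  total <- 0
  for (j in seq_len(k)) {
    fj <- cands[[j]]
    for (r in seq_len(nrow(fj))) {
      fs <- fj$start[r]; fe <- fj$end[r]
      prod_others <- 1
      for (i in seq_len(k)) {
        if (i == j) next
        df <- cands[[i]]
        # strictly after f in the tie-broken order (start, end, slot)
        later <- df$start > fs | (df$start == fs & df$end > fe) |
          (df$start == fs & df$end == fe & i > j)
        ok <- later & df$start <= fe + window
        prod_others <- prod_others * sum(ok)
        if (prod_others == 0) break
      }
      total <- total + prod_others
    }
  }
  total
}

#' Count cross-layer phrase matches in one document
#'
#' `#ph_D`: the number of distinct artifact tuples, one artifact matching
#' each component in that component's layer(s), that satisfy the window
#' constraint. The window is measured on base-layer token positions from
#' the end of the earliest artifact to the start of every other artifact
#' (the last artifact may end outside the window). Ordered phrases must
#' additionally consist of non-overlapping artifacts appearing
#' sequentially in component order.
#'
#' @param index A `collection_index`.
#' @param doc_id Document id.
#' @param components List of >= 2 term/list `query_node`s.
#' @param window Window size in base tokens, >= 1.
#' @param ordered Logical ordering flag.
#' @return Non-negative count.
#' @export
count_phrase_matches <- function(index, doc_id, components, window, ordered) {
  if (length(components) < 2L) stop("phrase needs at least 2 components")
  if (window < 1L) stop("window must be >= 1")
  cands <- lapply(components, component_candidates, index = index,
                  doc_id = doc_id)
  if (any(vapply(cands, nrow, integer(1)) == 0L)) return(0L)
  n <- if (ordered) count_ordered_tuples(cands, window)
       else count_unordered_tuples(cands, window)
  as.integer(n)
}

phrase_cache_key <- function(kind, node) {
  paste0(kind, "\r", render_node(node, with_weight = FALSE))
}

collection_phrase_count <- function(index, phrase) {
  key <- phrase_cache_key("ph", phrase)
  if (!is.null(index$cache[[key]])) return(index$cache[[key]])
  total <- 0
  for (doc_id in index$doc_ids) {
    total <- total + count_phrase_matches(index, doc_id, phrase$components,
                                          phrase$window, phrase$ordered)
  }
  index$cache[[key]] <- total
  total
}

#' Score a phrase query against one document
#'
#' Dirichlet-smoothed phrase likelihood: phrase-match counts take the
#' place of term counts, and the layer size is the size of the largest
#' layer stipulated by the phrase's components (document-side and
#' collection-side). The collection phrase count is evaluated lazily over
#' all documents and memoized on the index.
#'
#' @param index A `collection_index`.
#' @param phrase A phrase `query_node`.
#' @param doc_id Document id.
#' @param cfg A [smoothing_config()].
#' @return Probability in `[0, 1]`.
#' @export
score_phrase <- function(index, phrase, doc_id, cfg = smoothing_config()) {
  stopifnot(inherits(phrase, "query_node"), phrase$type == "phrase")
  layers <- unique(unlist(lapply(phrase$components, component_layers)))
  for (l in layers) get_layer(index, l) # fail fast on unindexed layers
  stopped <- cfg$use_stopped_text_sizes
  coll_sizes <- vapply(layers, collection_layer_size, numeric(1),
                       index = index, stopped = stopped)
  doc_sizes <- vapply(layers, index_layer_size, numeric(1), index = index,
                      doc_id = doc_id, stopped = stopped)
  if (cfg$phrase_denominator == "max") {
    coll_size <- max(coll_sizes)
    doc_size <- max(doc_sizes)
  } else {
    coll_size <- prod(coll_sizes)
    doc_size <- prod(doc_sizes)
  }
  if (coll_size == 0) {
    warning("all stipulated layers are empty collection-wide; scoring 0")
    return(0)
  }
  ph_c <- collection_phrase_count(index, phrase)
  if (ph_c == 0) return(0)
  ph_d <- count_phrase_matches(index, doc_id, phrase$components,
                               phrase$window, phrase$ordered)
  mu <- cfg$mu
  (ph_d + mu * ph_c / coll_size) / (doc_size + mu)
}

#' Score a list query against one document
#'
#' Standalone, a list is scored exactly as its members would be as
#' separate term queries: the product of the member probabilities
#' (members with no collection evidence are skipped, as they would be as
#' standalone terms). As a phrase component a list instead acts as a
#' disjunctive matcher; that path is exercised through
#' [count_phrase_matches()].
#'
#' @param index A `collection_index`.
#' @param lst A list `query_node`.
#' @param doc_id Document id.
#' @param cfg A [smoothing_config()].
#' @return Probability (product over members with evidence).
#' @export
score_list <- function(index, lst, doc_id, cfg = smoothing_config()) {
  stopifnot(inherits(lst, "query_node"), lst$type == "list")
  p <- 1
  any_evidence <- FALSE
  for (m in lst$members) {
    pm <- score_term(index, m, doc_id, cfg)
    if (pm > 0) {
      p <- p * pm
      any_evidence <- TRUE
    }
  }
  if (any_evidence) p else 0
}

# Does any artifact matching `pattern` overlap the token range
# [start, end)? "*" matches unconditionally.
pattern_overlaps <- function(index, pattern, doc_id, start, end) {
  if (identical(pattern, "*")) return(rep(TRUE, length(start)))
  sp <- artifact_spans(index, pattern$layer, pattern$value, doc_id)
  if (!nrow(sp)) return(rep(FALSE, length(start)))
  a_start <- sp$start
  a_end <- sp$start + sp$length
  vapply(seq_along(start), function(i) {
    any(pmax(a_start, start[i]) < pmin(a_end, end[i]))
  }, logical(1))
}

relation_match_count <- function(index, rel, doc_id) {
  rels <- relation_lookup(index, rel$layer, doc_id, rel$label)
  if (!nrow(rels)) return(0L)
  ok <- pattern_overlaps(index, rel$source, doc_id, rels$src_start,
                         rels$src_start + rels$src_len) &
    pattern_overlaps(index, rel$target, doc_id, rels$tgt_start,
                     rels$tgt_start + rels$tgt_len)
  sum(ok)
}

collection_relation_count <- function(index, rel) {
  key <- phrase_cache_key("rel", rel)
  if (!is.null(index$cache[[key]])) return(index$cache[[key]])
  total <- 0
  for (doc_id in index$doc_ids) {
    total <- total + relation_match_count(index, rel, doc_id)
  }
  index$cache[[key]] <- total
  total
}

#' Score a relation query against one document
#'
#' Counts relation artifacts whose label matches the pattern and whose
#' source and target spans overlap (token ranges intersect) some artifact
#' matching the source and target patterns respectively (`"*"` matches
#' unconditionally), then plugs that count into the Dirichlet-smoothed
#' term formula with the relation layer's sizes.
#'
#' @param index A `collection_index`.
#' @param rel A relation `query_node`.
#' @param doc_id Document id.
#' @param cfg A [smoothing_config()].
#' @return Probability in `[0, 1]`.
#' @export
score_relation <- function(index, rel, doc_id, cfg = smoothing_config()) {
  stopifnot(inherits(rel, "query_node"), rel$type == "relation")
  li <- get_layer(index, rel$layer)
  if (li$type != "relation") {
    stop(sprintf("layer \"%s\" is not a relation layer", rel$layer))
  }
  if (li$collection_size == 0) {
    warning(sprintf("relation layer \"%s\" is empty collection-wide; scoring 0",
                    rel$layer))
    return(0)
  }
  t_c <- collection_relation_count(index, rel)
  if (t_c == 0) return(0)
  t_d <- relation_match_count(index, rel, doc_id)
  mu <- mu_for(cfg, rel$layer)
  (t_d + mu * t_c / li$collection_size) /
    (unname(li$doc_sizes[doc_id]) + mu)
}

node_probability <- function(index, node, doc_id, cfg) {
  switch(node$type,
         term = score_term(index, node, doc_id, cfg),
         phrase = score_phrase(index, node, doc_id, cfg),
         relation = score_relation(index, node, doc_id, cfg),
         list = NA_real_, # handled member-wise by score_document
         stop(sprintf("unknown node type %s", node$type)))
}

is_query_stopword <- function(index, node, cfg) {
  cfg$drop_stopword_terms && node$type == "term" &&
    identical(node$layer, "text") &&
    (if (index$config$lowercase) tolower(node$value) else node$value) %in%
      index$config$stopwords
}

# Flatten a query into scoreable units: standalone lists contribute their
# members individually (each inheriting the list's weight); everything
# else contributes itself. Stopword text terms are dropped when the config
# asks for query-side stopping.
scoreable_units <- function(index, q, cfg) {
  units <- list()
  for (node in q$nodes) {
    if (node$type == "list") {
      for (m in node$members) {
        m$weight <- node$weight
        if (!is_query_stopword(index, m, cfg)) units <- c(units, list(m))
      }
    } else if (!is_query_stopword(index, node, cfg)) {
      units <- c(units, list(node))
    }
  }
  units
}

#' Score a full query against one document
#'
#' The document score is the weighted sum of log node probabilities,
#' `sum(weight * log P(node | D))`, with a uniform document prior dropped.
#' Nodes with zero collection evidence contribute nothing (they are
#' skipped rather than scored `-Inf`, so a single out-of-collection term
#' never annihilates a document).
#'
#' @param index A `collection_index`.
#' @param q A `layer_query` (or query string, parsed on the fly).
#' @param doc_id Document id.
#' @param cfg A [smoothing_config()].
#' @return A `scored_doc`: list with `doc_id`, `score`, and
#'   `contributions` (data.frame of node, log-probability, weight).
#' @export
score_document <- function(index, q, doc_id, cfg = smoothing_config()) {
  if (is.character(q)) q <- parse_query(q)
  units <- scoreable_units(index, q, cfg)
  node_str <- character()
  logp <- numeric()
  wts <- numeric()
  for (u in units) {
    p <- node_probability(index, u, doc_id, cfg)
    if (p <= 0) {
      if (cfg$verbose) {
        message(sprintf("skipping zero-evidence node: %s", render_node(u)))
      }
      next
    }
    node_str <- c(node_str, render_node(u, with_weight = FALSE))
    logp <- c(logp, log(p))
    wts <- c(wts, u$weight)
  }
  structure(list(doc_id = doc_id,
                 score = sum(wts * logp),
                 contributions = data.frame(node = node_str, logp = logp,
                                            weight = wts,
                                            stringsAsFactors = FALSE)),
            class = "scored_doc")
}

#' Rank the collection for a query
#'
#' Scores every document and returns the top `k` by descending score, ties
#' broken by ascending document id (deterministic).
#'
#' @param index A `collection_index`.
#' @param q A `layer_query` or query string.
#' @param cfg A [smoothing_config()].
#' @param k Cutoff, >= 1 (default 1000).
#' @return Data.frame with columns `doc_id`, `score`, `rank`.
#' @export
rank_documents <- function(index, q, cfg = smoothing_config(), k = 1000L) {
  stopifnot(k >= 1L)
  if (is.character(q)) q <- parse_query(q)
  scores <- vapply(index$doc_ids, function(d) {
    score_document(index, q, d, cfg)$score
  }, numeric(1))
  ord <- order(-scores, index$doc_ids)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(doc_id = index$doc_ids[ord], score = unname(scores[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
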