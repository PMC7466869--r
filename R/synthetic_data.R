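# Synthetic layered corpora with the statistical shape of clinical NLP
# pipeline output: base tokens from a topic-mixture unigram model,
# multi-word named entities mapped to concept (CUI) and semantic-type
# (TUI) identifiers by longest-match dictionary tagging, lemma and POS
# layers aligned one-to-one with tokens, and random dependency trees per
# sentence. No clinical realism is claimed; the generator exists so every
# retrieval stage is testable without restricted clinical data.

# Run code under a fixed seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Concept dictionary
#'
#' Maps surface forms (1-3 token phrases) to concept identifiers (CUIs)
#' and semantic-type identifiers (TUIs). CUIs are unique per surface form
#' and every CUI has exactly one TUI (the CUI -> TUI mapping is
#' many-to-one). A lemma map normalizes individual tokens.
#'
#' @param entries Data.frame with columns `surface` (space-joined token
#'   phrase), `cui`, `tui`.
#' @param lemma_map Named character vector token -> lemma (tokens absent
#'   from the map lemmatize to themselves).
#' @return A `concept_dictionary`.
#' @export
concept_dictionary <- function(entries, lemma_map = character()) {
  stopifnot(all(c("surface", "cui", "tui") %in% names(entries)))
  entries <- data.frame(surface = as.character(entries$surface),
                        cui = as.character(entries$cui),
                        tui = as.character(entries$tui),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(entries$surface)) {
    stop(sprintf("duplicate surface form: %s",
                 entries$surface[duplicated(entries$surface)][1]))
  }
  tui_by_cui <- tapply(entries$tui, entries$cui,
                       function(x) length(unique(x)))
  if (any(tui_by_cui > 1L)) {
    stop("every CUI must map to exactly one TUI")
  }
  structure(list(entries = entries, lemma_map = lemma_map),
            class = "concept_dictionary")
}

#' @export
print.concept_dictionary <- function(x, ...) {
  cat(sprintf("<concept_dictionary: %d surface form(s), %d TUI group(s)>\n",
              nrow(x$entries), length(unique(x$entries$tui))))
  invisible(x)
}

#' Fixture dictionary with the worked-example concepts
#'
#' A tiny dictionary binding familiar obstetric and hepatitis concepts to
#' their surface forms (pregnancy, preterm delivery, delivery, hepatitis
#' c, hepatitis), so worked-example tests and demos read naturally. The
#' TUI assignments are synthetic placeholders, not UMLS values.
#'
#' @return A `concept_dictionary`.
#' @export
fixture_dictionary <- function() {
  concept_dictionary(data.frame(
    surface = c("pregnancy", "preterm delivery", "delivery",
                "hepatitis c", "hepatitis"),
    cui = c("C0032961", "C0151526", "C0011209", "C0019196", "C0019158"),
    tui = c("T040", "T046", "T040", "T047", "T047"),
    stringsAsFactors = FALSE
  ))
}

#' Synthetic corpus generator configuration
#'
#' Defaults describe a desk-scale stand-in for a patient-visit collection:
#' a few dozen documents of tens of tokens, a small concept dictionary,
#' and a handful of topics with a fixed planting rate. The same seed
#' always yields a byte-identical corpus.
#'
#' @param seed Integer RNG seed.
#' @param n_docs Number of documents (>= 0).
#' @param tokens_per_doc Length-2 integer range of document lengths.
#' @param vocab_size Vocabulary size (>= 1).
#' @param n_concepts Number of dictionary concepts.
#' @param n_topics Number of topics.
#' @param topic_concepts Concepts per topic.
#' @param planting_rate Probability a document is planted for some topic
#'   (its relevance label), in `[0, 1]`.
#' @param n_inserts How many times each topic concept's surface form is
#'   inserted into a planted document.
#' @param background_concept_rate Probability a background document gets
#'   one random concept mention (distractor mentions).
#' @param inflect_rate Probability a background token is pluralized with
#'   "s" (exercises the lemma layer).
#' @param pos_tags POS tagset sampled per token.
#' @param dep_labels Dependency labels sampled per edge.
#' @param sentence_len Tokens per sentence (dependency trees are built per
#'   sentence).
#' @return A `generator_config`.
#' @export
generator_config <- function(seed = 42L, n_docs = 60L,
                             tokens_per_doc = c(40L, 80L),
                             vocab_size = 150L, n_concepts = 12L,
                             n_topics = 6L, topic_concepts = 2L,
                             planting_rate = 0.2, n_inserts = 2L,
                             background_concept_rate = 0.5,
                             inflect_rate = 0.1,
                             pos_tags = c("NN", "VB", "JJ", "IN", "DT",
                                          "NNP", "RB"),
                             dep_labels = c("nsubj", "dobj", "amod",
                                            "advmod", "prep", "det"),
                             sentence_len = 10L) {
  stopifnot(n_docs >= 0L, length(tokens_per_doc) == 2L,
            all(tokens_per_doc >= 1L),
            tokens_per_doc[1] <= tokens_per_doc[2],
            vocab_size >= 1L, n_concepts >= 1L, n_topics >= 1L,
            topic_concepts >= 1L, planting_rate >= 0, planting_rate <= 1,
            n_inserts >= 1L, sentence_len >= 2L, length(pos_tags) >= 1L,
            length(dep_labels) >= 1L)
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 tokens_per_doc = as.integer(tokens_per_doc),
                 vocab_size = as.integer(vocab_size),
                 n_concepts = as.integer(n_concepts),
                 n_topics = as.integer(n_topics),
                 topic_concepts = as.integer(topic_concepts),
                 planting_rate = planting_rate,
                 n_inserts = as.integer(n_inserts),
                 background_concept_rate = background_concept_rate,
                 inflect_rate = inflect_rate,
                 pos_tags = pos_tags, dep_labels = dep_labels,
                 sentence_len = as.integer(sentence_len)),
            class = "generator_config")
}

# Deterministic pronounceable pseudo-vocabulary: words are base-20
# spellings over 20 syllables, so they are unique by construction.
make_vocabulary <- function(n) {
  syl <- c("ba", "co", "di", "fa", "gu", "he", "ki", "lo", "mu", "ne",
           "pa", "re", "si", "to", "vu", "wa", "xe", "yo", "za", "bri")
  vapply(seq_len(n) - 1L, function(i) {
    w <- syl[(i %% 20L) + 1L]
    i <- i %/% 20L
    while (i > 0L) {
      w <- paste0(syl[(i %% 20L) + 1L], w)
      i <- i %/% 20L
    }
    w
  }, character(1))
}

sample_concepts <- function(cfg, vocab) {
  surfaces <- character(0)
  lens <- sample(c(1L, 2L, 3L), cfg$n_concepts, replace = TRUE,
                 prob = c(0.3, 0.5, 0.2))
  for (len in lens) {
    repeat {
      s <- paste(sample(vocab, len), collapse = " ")
      if (!s %in% surfaces) break
    }
    surfaces <- c(surfaces, s)
  }
  n_tuis <- max(1L, ceiling(cfg$n_concepts / 3))
  data.frame(
    surface = surfaces,
    cui = sprintf("C%07d", 1000000L + seq_len(cfg$n_concepts)),
    tui = sprintf("T%03d", sample.int(n_tuis, cfg$n_concepts,
                                      replace = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Dictionary-based concept tagging
#'
#' Longest-match, left-to-right named-entity tagging: at every start
#' position the longest matching dictionary surface form is emitted as a
#' concept (CUI) artifact with a matching semantic-type (TUI) artifact;
#' the scan then advances one token, so entries overlapping a previous
#' match are still found. Deterministic.
#'
#' @param tokens Character vector of base-layer tokens.
#' @param dict A [concept_dictionary()].
#' @return List with `cui` and `tui` artifact data.frames (columns
#'   `value`, `start`, `length`).
#' @examples
#' tag_concepts(c("pregnancy", "with", "preterm", "delivery"),
#'              fixture_dictionary())
#' @export
tag_concepts <- function(tokens, dict) {
  entry_tokens <- strsplit(dict$entries$surface, " ", fixed = TRUE)
  max_len <- if (length(entry_tokens)) {
    max(vapply(entry_tokens, length, integer(1)))
  } else 0L
  surface_key <- vapply(entry_tokens, paste, character(1), collapse = " ")
  cui <- character(); tui <- character()
  start <- integer(); length_ <- integer()
  n <- length(tokens)
  for (i in seq_len(n)) {
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      hit <- match(key, surface_key)
      if (!is.na(hit)) {
        cui <- c(cui, dict$entries$cui[hit])
        tui <- c(tui, dict$entries$tui[hit])
        start <- c(start, i - 1L)
        length_ <- c(length_, len)
        break
      }
    }
  }
  list(cui = data.frame(value = cui, start = start, length = length_,
                        stringsAsFactors = FALSE),
       tui = data.frame(value = tui, start = start, length = length_,
                        stringsAsFactors = FALSE))
}

# Decode a Pruefer sequence into an edge list; with the sequence sampled
# uniformly this yields a uniformly random labelled spanning tree.
prufer_tree <- function(m) {
  if (m == 2L) return(cbind(1L, 2L))
  pruf <- sample.int(m, m - 2L, replace = TRUE)
  degree <- rep(1L, m)
  for (v in pruf) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, nrow = m - 1L, ncol = 2L)
  ptr <- 1L
  for (i in seq_along(pruf)) {
    leaf <- which(degree == 1L)[1]
    edges[ptr, ] <- c(pruf[i], leaf)
    ptr <- ptr + 1L
    degree[leaf] <- 0L
    degree[pruf[i]] <- degree[pruf[i]] - 1L
  }
  edges[ptr, ] <- which(degree == 1L)
  edges
}

# Orient an undirected tree away from a root: each edge becomes
# (head = parent, dependent = child).
orient_tree <- function(edges, m, root = 1L) {
  adj <- vector("list", m)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, m)
  queue <- root
  seen <- logical(m)
  seen[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  children <- setdiff(seq_len(m), root)
  cbind(head = parent[children], dependent = children)
}

make_dep_layer <- function(n_tokens, cfg) {
  if (n_tokens < 2L) return(empty_relation_frame())
  bounds <- seq(0L, n_tokens, by = cfg$sentence_len)
  if (bounds[length(bounds)] < n_tokens) bounds <- c(bounds, n_tokens)
  out <- empty_relation_frame()
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]
    m <- bounds[s + 1L] - lo
    if (m < 2L) next
    edges <- orient_tree(prufer_tree(m), m)
    labels <- sample(cfg$dep_labels, nrow(edges), replace = TRUE)
    out <- rbind(out, data.frame(
      value = labels,
      src_start = lo + edges[, "head"] - 1L, src_len = 1L,
      tgt_start = lo + edges[, "dependent"] - 1L, tgt_len = 1L,
      stringsAsFactors = FALSE
    ))
  }
  out
}

insert_phrase <- function(tokens, phrase_tokens) {
  at <- sample.int(length(tokens) + 1L, 1L)
  append(tokens, phrase_tokens, after = at - 1L)
}

#' Generate a synthetic layered corpus
#'
#' Documents draw base tokens from a Zipf unigram model over a pseudo-word
#' vocabulary; a fraction (`planting_rate`) of documents is planted for a
#' topic and has that topic's concept surface forms inserted. The final
#' token streams are annotated by longest-match dictionary tagging (cui
#' and tui layers, multi-word spans included), token-aligned lemma and POS
#' layers, and per-sentence uniformly random dependency trees. Identical
#' configuration (including seed) yields an identical corpus.
#'
#' @param cfg A [generator_config()].
#' @return A `synthetic_corpus`: list with `docs` (layered documents),
#'   `dictionary` (the [concept_dictionary()]), `doc_topics` (per-document
#'   planted topic id, `NA` for background documents), `topic_concepts`
#'   (list topic id -> dictionary row indices), and `config`.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$vocab_size < cfg$n_concepts) {
    stop("vocabulary smaller than the number of concept surface forms")
  }
  local_seed(cfg$seed, {
    vocab <- make_vocabulary(cfg$vocab_size)
    entries <- sample_concepts(cfg, vocab)
    lemma_map <- stats::setNames(stem_suffix_s(vocab), vocab)
    dict <- concept_dictionary(entries, lemma_map)
    topic_ids <- sprintf("%d", 100L + seq_len(cfg$n_topics))
    topic_concepts <- stats::setNames(lapply(seq_len(cfg$n_topics), function(i) {
      sample.int(cfg$n_concepts, min(cfg$topic_concepts, cfg$n_concepts))
    }), topic_ids)
    # one non-concept context token per topic: stays textual in every
    # formulation, like the free-text words around named entities
    topic_context <- stats::setNames(sample(vocab, cfg$n_topics,
                                            replace = TRUE), topic_ids)
    zipf <- (1 / seq_len(cfg$vocab_size))
    zipf <- zipf / sum(zipf)
    docs <- vector("list", cfg$n_docs)
    doc_topics <- rep(NA_character_, cfg$n_docs)
    for (d in seq_len(cfg$n_docs)) {
      n_tok <- sample(seq(cfg$tokens_per_doc[1], cfg$tokens_per_doc[2]), 1L)
      tokens <- sample(vocab, n_tok, replace = TRUE, prob = zipf)
      plural <- stats::runif(n_tok) < cfg$inflect_rate
      tokens[plural] <- paste0(tokens[plural], "s")
      if (stats::runif(1) < cfg$planting_rate) {
        topic <- sample(topic_ids, 1L)
        doc_topics[d] <- topic
        for (ci in topic_concepts[[topic]]) {
          phrase <- strsplit(entries$surface[ci], " ", fixed = TRUE)[[1]]
          for (rep_i in seq_len(cfg$n_inserts)) {
            tokens <- insert_phrase(tokens, phrase)
          }
        }
        tokens <- insert_phrase(tokens, topic_context[[topic]])
      } else if (stats::runif(1) < cfg$background_concept_rate) {
        ci <- sample.int(cfg$n_concepts, 1L)
        phrase <- strsplit(entries$surface[ci], " ", fixed = TRUE)[[1]]
        tokens <- insert_phrase(tokens, phrase)
      }
      tagged <- tag_concepts(tokens, dict)
      lemmas <- unname(ifelse(tokens %in% names(lemma_map),
                              lemma_map[tokens], stem_suffix_s(tokens)))
      n_fin <- length(tokens)
      docs[[d]] <- layered_document(
        doc_id = sprintf("doc%04d", d),
        tokens = tokens,
        layers = list(
          cui = tagged$cui,
          tui = tagged$tui,
          lemma = data.frame(value = lemmas,
                             start = seq_len(n_fin) - 1L, length = 1L,
                             stringsAsFactors = FALSE),
          pos = data.frame(value = sample(cfg$pos_tags, n_fin,
                                          replace = TRUE),
                           start = seq_len(n_fin) - 1L, length = 1L,
                           stringsAsFactors = FALSE)
        ),
        relations = list(dep = make_dep_layer(n_fin, cfg))
      )
    }
    structure(list(docs = docs, dictionary = dict, doc_topics = doc_topics,
                   topic_concepts = topic_concepts,
                   topic_context = topic_context, config = cfg),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d docs, %d concepts, %d topics, %d planted>\n",
              length(x$docs), nrow(x$dictionary$entries),
              length(x$topic_concepts), sum(!is.na(x$doc_topics))))
  invisible(x)
}

#' Derive topics and qrels from a synthetic corpus
#'
#' Each topic's text is the space-joined surface forms of its concept set;
#' relevance is the planted topic assignment recorded at generation time
#' (never re-derived by retrieval), so qrels are retrieval-independent.
#' The qrels contain a judgment for every (topic, document) pair: grade 1
#' for planted matches, 0 otherwise.
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @return List with `topics` (data.frame `topic_id`, `text`) and `qrels`
#'   (data.frame `topic`, `doc_id`, `grade`).
#' @export
generate_topics_and_qrels <- function(corpus) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dict <- corpus$dictionary
  topic_ids <- names(corpus$topic_concepts)
  topics <- data.frame(
    topic_id = topic_ids,
    text = vapply(topic_ids, function(t) {
      paste(c(dict$entries$surface[corpus$topic_concepts[[t]]],
              corpus$topic_context[[t]]), collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  doc_ids <- vapply(corpus$docs, function(d) d$doc_id, character(1))
  qrels <- do.call(rbind, lapply(topic_ids, function(t) {
    data.frame(topic = t, doc_id = doc_ids,
               grade = as.integer(!is.na(corpus$doc_topics) &
                                    corpus$doc_topics == t),
               stringsAsFactors = FALSE)
  }))
  row.names(qrels) <- NULL
  list(topics = topics, qrels = qrels)
}

#' Render a topic as a query string in a given formulation
#'
#' The synthetic world knows its own concept mapping, so it can emit the
#' pre-rewritten query strings the different formulations expect: `TXT`
#' (plain text terms), `CUI` (one concept-identifier term per topic
#' concept), `MIX` (text terms with each concept replaced by its CUI
#' term), and `PH-LS` (per concept, a list of the CUI and the concept's
#' first surface token). The `-MRF` variants of these are produced by
#' applying [sdm_expand()] to the rendered atoms.
#'
#' @param corpus A `synthetic_corpus`.
#' @param topic_id Topic id present in the corpus.
#' @param formulation One of `"TXT"`, `"CUI"`, `"MIX"`, `"PH-LS"`.
#' @return Query string in the aligned-layer dialect.
#' @export
topic_query <- function(corpus, topic_id,
                        formulation = c("TXT", "CUI", "MIX", "PH-LS")) {
  formulation <- match.arg(formulation)
  ci <- corpus$topic_concepts[[topic_id]]
  if (is.null(ci)) stop(sprintf("unknown topic id: %s", topic_id))
  entries <- corpus$dictionary$entries[ci, , drop = FALSE]
  context <- corpus$topic_context[[topic_id]]
  per_concept <- switch(formulation,
    "TXT" = entries$surface,
    "CUI" = paste0("cui:", entries$cui),
    "MIX" = paste0("cui:", entries$cui),
    "PH-LS" = {
      first_tok <- vapply(strsplit(entries$surface, " ", fixed = TRUE),
                          `[`, character(1), 1L)
      sprintf("#l(cui:%s|%s)", entries$cui, first_tok)
    })
  # the context token stays textual everywhere except the entity-only
  # CUI formulation, mirroring how free-text words around named
  # entities survive concept rewriting
  atoms <- if (formulation == "CUI") per_concept else c(per_concept, context)
  paste(atoms, collapse = " ")
}
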