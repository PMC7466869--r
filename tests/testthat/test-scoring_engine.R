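# The frozen expected values below were computed by hand from the
# smoothing formulas (see the corresponding comments).

test_that("term scoring matches hand-evaluated Dirichlet smoothing", {
  # build a collection realizing #t_D=2, |D|_a=10, #t_C=5, |C|_a=100:
  # doc A has 2 x's among 10 tokens; doc B has 3 x's among 90 tokens.
  dA <- layered_document("A", c(rep("x", 2), rep("f0", 8)))
  dB <- layered_document("B", c(rep("x", 3), rep("f1", 87)))
  idx <- build_index(list(dA, dB))
  cfg <- smoothing_config(mu = 10)
  # (2 + 10 * 5/100) / (10 + 10) = 0.125
  expect_equal(score_term(idx, term_node("text", "x"), "A", cfg), 0.125)
  # absent everywhere -> 0 (never negative/smoothed)
  expect_identical(score_term(idx, term_node("text", "zzz"), "A", cfg), 0)
  # mu -> 0 recovers maximum likelihood #t_D / |D|
  expect_equal(score_term(idx, term_node("text", "x"), "A",
                          smoothing_config(mu = 1e-9)), 2 / 10,
               tolerance = 1e-8)
  # empty layer collection-wide warns and scores 0
  dE <- layered_document("E", c("a"),
                         layers = list(cui = data.frame(
                           value = character(), start = integer(),
                           length = integer())))
  idxE <- build_index(list(dE))
  expect_warning(p <- score_term(idxE, term_node("cui", "C1"), "E", cfg),
                 "empty")
  expect_identical(p, 0)
})

test_that("Dirichlet term probabilities are a proper distribution per layer", {
  docs <- random_layered_corpus(seed = 31, n_docs = 6)
  idx <- build_index(docs, tokenizer_config())
  cfg <- smoothing_config(mu = 7)
  for (lname in c("text", "cui")) {
    vocab <- names(idx$layers[[lname]]$postings)
    for (doc_id in idx$doc_ids[1:3]) {
      total <- sum(vapply(vocab, function(v) {
        score_term(idx, term_node(lname, v), doc_id, cfg)
      }, numeric(1)))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("phrase matching honours window, order, and cross-layer spans", {
  idx <- build_index(list(fig_document()))
  pre_del <- list(term_node("text", "preterm"), term_node("text", "delivery"))
  expect_identical(count_phrase_matches(idx, "visitA", pre_del, 8, TRUE), 1L)
  expect_identical(count_phrase_matches(idx, "visitA", rev(pre_del), 8,
                                        TRUE), 0L)
  expect_identical(count_phrase_matches(idx, "visitA", rev(pre_del), 8,
                                        FALSE), 1L)
  # cross-layer: token "pregnancy" then the multi-word NE starting at 2
  cross <- list(term_node("text", "pregnancy"),
                term_node("cui", "C0151526"))
  expect_identical(count_phrase_matches(idx, "visitA", cross, 4, TRUE), 1L)
  # window measured end-of-first to start-of-others: the NE at 2 starts
  # 1 token after "pregnancy" ends, so window 1 admits it, window short no
  expect_identical(count_phrase_matches(idx, "visitA", cross, 1, TRUE), 1L)
  adjacent <- list(term_node("text", "with"), term_node("cui", "C0151526"))
  expect_identical(count_phrase_matches(idx, "visitA", adjacent, 1, TRUE),
                   1L)
})

test_that("phrase scoring matches the hand-evaluated smoothed estimate", {
  # 1-doc collection, #ph_D = 1, text only, |D|_text = 4, mu = 10:
  # (1 + 10 * 1/4) / (4 + 10) = 0.25
  idx <- build_index(list(fig_document()))
  ph <- phrase_node(8, TRUE, list(term_node("text", "preterm"),
                                  term_node("text", "delivery")))
  expect_equal(score_phrase(idx, ph, "visitA", smoothing_config(mu = 10)),
               0.25)
  never <- phrase_node(8, TRUE, list(term_node("text", "delivery"),
                                     term_node("text", "pregnancy")))
  expect_identical(score_phrase(idx, never, "visitA",
                                smoothing_config(mu = 10)), 0)
})

test_that("phrase counts are monotone in window and ordering", {
  docs <- random_layered_corpus(seed = 41, n_docs = 6)
  idx <- build_index(docs, tokenizer_config())
  comps_pool <- list(
    list(term_node("text", "alpha"), term_node("text", "beta")),
    list(term_node("text", "gamma"), term_node("cui", "C1")),
    list(term_node("text", "alpha"), term_node("text", "beta"),
         term_node("cui", "C2"))
  )
  for (comps in comps_pool) {
    for (doc_id in idx$doc_ids) {
      prev_o <- 0; prev_u <- 0
      for (w in c(1, 2, 4, 8, 16)) {
        o <- count_phrase_matches(idx, doc_id, comps, w, TRUE)
        u <- count_phrase_matches(idx, doc_id, comps, w, FALSE)
        expect_gte(o, prev_o)
        expect_gte(u, prev_u)
        expect_gte(u, o)
        prev_o <- o; prev_u <- u
      }
    }
  }
})

test_that("list queries score as independent members and match disjunctively", {
  docs <- random_layered_corpus(seed = 17, n_docs = 5)
  idx <- build_index(docs, tokenizer_config())
  cfg <- smoothing_config(mu = 5)
  lst <- list_node(list(term_node("text", "alpha"), term_node("cui", "C1")))
  for (doc_id in idx$doc_ids) {
    expect_equal(score_list(idx, lst, doc_id, cfg),
                 score_term(idx, term_node("text", "alpha"), doc_id, cfg) *
                   score_term(idx, term_node("cui", "C1"), doc_id, cfg))
  }
  # singleton list is the member, in both standalone and phrase contexts
  single <- list_node(list(term_node("text", "alpha")))
  for (doc_id in idx$doc_ids) {
    expect_equal(score_list(idx, single, doc_id, cfg),
                 score_term(idx, term_node("text", "alpha"), doc_id, cfg))
    comps_t <- list(term_node("text", "alpha"), term_node("text", "beta"))
    comps_l <- list(single, term_node("text", "beta"))
    expect_identical(count_phrase_matches(idx, doc_id, comps_l, 8, FALSE),
                     count_phrase_matches(idx, doc_id, comps_t, 8, FALSE))
  }
  # disjunctive matcher: list component matches where any member matches
  idxf <- build_index(list(fig_document()))
  comps <- list(term_node("text", "pregnancy"),
                list_node(list(term_node("cui", "C9999999"),
                               term_node("text", "preterm"))))
  expect_identical(count_phrase_matches(idxf, "visitA", comps, 8, TRUE), 1L)
})

test_that("relation queries count label and endpoint-overlap matches", {
  d <- layered_document(
    "r1", c("gave", "mr", "plavix", "daily"),
    layers = list(lemma = data.frame(value = c("give", "mr", "plavix",
                                               "daily"),
                                     start = 0:3, length = 1L),
                  pos = data.frame(value = c("VBD", "NNP", "NNP", "RB"),
                                   start = 0:3, length = 1L)),
    relations = list(dep = data.frame(
      value = c("dobj", "advmod"),
      src_start = c(0L, 0L), src_len = 1L,
      tgt_start = c(2L, 3L), tgt_len = 1L)))
  idx <- build_index(list(d))
  cfg <- smoothing_config(mu = 4)
  give_nnp <- relation_node("dep", "*", term_node("lemma", "give"),
                            term_node("pos", "NNP"))
  # only the dobj edge targets an NNP token
  expect_equal(score_relation(idx, give_nnp, "r1", cfg),
               (1 + 4 * 1 / 2) / (2 + 4))
  allw <- relation_node("dep", "*", "*", "*")
  expect_equal(score_relation(idx, allw, "r1", cfg), (2 + 4 * 1) / (2 + 4))
  lab <- relation_node("dep", "advmod", "*", "*")
  expect_equal(score_relation(idx, lab, "r1", cfg), (1 + 4 * 0.5) / (2 + 4))
  none <- relation_node("dep", "nsubj", "*", "*")
  expect_identical(score_relation(idx, none, "r1", cfg), 0)
})

test_that("document scores combine weighted logs and skip zero evidence", {
  docs <- random_layered_corpus(seed = 23, n_docs = 5)
  idx <- build_index(docs, tokenizer_config())
  cfg <- smoothing_config(mu = 9)
  q <- parse_query("alpha^2 cui:C1 zzz_not_there")
  for (doc_id in idx$doc_ids) {
    sd <- score_document(idx, q, doc_id, cfg)
    manual <- 2 * log(score_term(idx, term_node("text", "alpha"), doc_id,
                                 cfg)) +
      log(score_term(idx, term_node("cui", "C1"), doc_id, cfg))
    expect_equal(sd$score, manual)
    expect_false("zzz_not_there" %in% sd$contributions$node)
  }
  # all-OOV query: defined, all zero
  sd0 <- score_document(idx, "nope1 nope2", idx$doc_ids[1], cfg)
  expect_identical(sd0$score, 0)
})

test_that("doubling all weights preserves ranking order", {
  docs <- random_layered_corpus(seed = 29, n_docs = 8)
  idx <- build_index(docs, tokenizer_config())
  q1 <- parse_query("alpha beta cui:C1")
  q2 <- parse_query("alpha^2 beta^2 cui:C1^2")
  r1 <- rank_documents(idx, q1, smoothing_config(mu = 6), k = 8)
  r2 <- rank_documents(idx, q2, smoothing_config(mu = 6), k = 8)
  expect_identical(r1$doc_id, r2$doc_id)
  expect_equal(r2$score, 2 * r1$score)
})

test_that("ranking is deterministic with doc-id tie-breaks", {
  # two identical docs tie exactly; order must be ascending doc_id
  d1 <- layered_document("zeta", c("a", "b"))
  d2 <- layered_document("alpha", c("a", "b"))
  d3 <- layered_document("mid", c("c", "c"))
  idx <- build_index(list(d1, d2, d3))
  r <- rank_documents(idx, "a", smoothing_config(mu = 2), k = 3)
  expect_identical(r$doc_id[1:2], c("alpha", "zeta"))
  expect_identical(r$rank, 1:3)
  # only the docs containing the term outrank the rest
  expect_identical(r$doc_id[3], "mid")
})

test_that("mu -> Inf collapses term probabilities to collection proportions", {
  docs <- random_layered_corpus(seed = 37, n_docs = 6)
  idx <- build_index(docs, tokenizer_config())
  big <- smoothing_config(mu = 1e12)
  t_c <- collection_layer_size(idx, "text")
  f <- idx$layers$text$collection_freq[["alpha"]]
  for (doc_id in idx$doc_ids) {
    expect_equal(score_term(idx, term_node("text", "alpha"), doc_id, big),
                 f / t_c, tolerance = 1e-6)
  }
})

test_that("stopword handling: query-side stopping and size flags", {
  cfg_tok <- tokenizer_config(stopwords = c("with"))
  d <- fig_document()
  idx <- build_index(list(d), cfg_tok)
  cfg <- smoothing_config(mu = 10)
  # "with" is dropped from the query, contributing nothing
  sd <- score_document(idx, "preterm with", "visitA", cfg)
  expect_identical(nrow(sd$contributions), 1L)
  # but it stays indexed: sizes count it by default
  expect_identical(index_layer_size(idx, "text", "visitA"), 4)
  expect_identical(index_layer_size(idx, "text", "visitA", stopped = TRUE),
                   3)
  keep <- smoothing_config(mu = 10, drop_stopword_terms = FALSE)
  sd2 <- score_document(idx, "preterm with", "visitA", keep)
  expect_identical(nrow(sd2$contributions), 2L)
  # stopped sizes flow into the denominator when requested
  st <- smoothing_config(mu = 10, use_stopped_text_sizes = TRUE,
                         drop_stopword_terms = FALSE)
  expect_equal(score_term(idx, term_node("text", "preterm"), "visitA", st),
               (1 + 10 * 1 / 3) / (3 + 10))
})
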