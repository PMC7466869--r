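test_that("generated corpora validate and are byte-identical under a seed", {
  cfg <- generator_config(seed = 101L, n_docs = 12L)
  corp <- generate_corpus(cfg)
  expect_length(corp$docs, 12L)
  for (d in corp$docs) expect_identical(validate_document(d), character(0))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_layered_jsonl(corp$docs, p1)
  write_layered_jsonl(generate_corpus(cfg)$docs, p2)
  expect_identical(readLines(p1), readLines(p2))
  # different seed, different corpus
  other <- generate_corpus(generator_config(seed = 102L, n_docs = 12L))
  expect_false(identical(corp$docs, other$docs))
})

test_that("the dictionary is many-to-one on TUIs and tagging is longest-match", {
  corp <- generate_corpus(generator_config(seed = 7L, n_docs = 10L))
  dict <- corp$dictionary
  tui_per_cui <- tapply(dict$entries$tui, dict$entries$cui,
                        function(x) length(unique(x)))
  expect_true(all(tui_per_cui == 1L))
  expect_false(anyDuplicated(dict$entries$surface) > 0)
  # re-tagging stored token streams reproduces the cui layer exactly
  for (d in corp$docs) {
    again <- layerlm:::tag_concepts(d$tokens, dict)
    expect_identical(d$layers$cui,
                     layerlm:::sort_artifact_frame(again$cui))
  }
})

test_that("multi-word surface forms yield spans longer than one token", {
  cfg <- generator_config(seed = 13L, n_docs = 25L, planting_rate = 0.5)
  corp <- generate_corpus(cfg)
  multi <- corp$dictionary$entries$surface[
    vapply(strsplit(corp$dictionary$entries$surface, " "), length,
           integer(1)) > 1]
  lens <- unlist(lapply(corp$docs, function(d) d$layers$cui$length))
  if (length(multi)) expect_gt(max(lens), 1L)
  # lemma and pos layers align one-to-one with tokens
  for (d in corp$docs[1:5]) {
    expect_identical(nrow(d$layers$lemma), length(d$tokens))
    expect_identical(nrow(d$layers$pos), length(d$tokens))
    expect_true(all(d$layers$lemma$length == 1L))
  }
})

test_that("dependency trees span each sentence exactly once", {
  cfg <- generator_config(seed = 19L, n_docs = 6L, sentence_len = 8L)
  corp <- generate_corpus(cfg)
  for (d in corp$docs) {
    rels <- d$relations$dep
    n <- length(d$tokens)
    # a tree over m nodes has m - 1 edges; summed over sentences that is
    # n - (number of sentences with >= 2 tokens adjusted for remainders)
    bounds <- unique(c(seq(0L, n, by = 8L), n))
    expected <- sum(pmax(diff(bounds) - 1L, 0L))
    expect_identical(nrow(rels), expected)
    # every dependent has exactly one head
    expect_false(anyDuplicated(rels$tgt_start) > 0)
  }
})

test_that("qrels reflect planted assignments, not retrieval", {
  cfg <- generator_config(seed = 23L, n_docs = 30L, planting_rate = 0.4)
  corp <- generate_corpus(cfg)
  tq <- generate_topics_and_qrels(corp)
  expect_identical(nrow(tq$topics), corp$config$n_topics)
  for (i in seq_along(corp$docs)) {
    t <- corp$doc_topics[i]
    id <- corp$docs[[i]]$doc_id
    rel_rows <- tq$qrels[tq$qrels$doc_id == id & tq$qrels$grade >= 1L, ]
    if (is.na(t)) expect_identical(nrow(rel_rows), 0L)
    else expect_identical(rel_rows$topic, t)
  }
  # planting rate 0 -> no relevant documents at all
  none <- generate_corpus(generator_config(seed = 5L, n_docs = 10L,
                                           planting_rate = 0))
  expect_true(all(generate_topics_and_qrels(none)$qrels$grade == 0L))
})

test_that("token frequencies track the configured Zipf unigram model", {
  cfg <- generator_config(seed = 31L, n_docs = 300L,
                          tokens_per_doc = c(40L, 60L), vocab_size = 20L,
                          n_concepts = 3L, planting_rate = 0,
                          background_concept_rate = 0, inflect_rate = 0)
  corp <- generate_corpus(cfg)
  tokens <- unlist(lapply(corp$docs, `[[`, "tokens"))
  expect_gt(length(tokens), 1e4)
  vocab <- layerlm:::make_vocabulary(20L)
  p <- (1 / seq_len(20)) / sum(1 / seq_len(20))
  obs <- table(factor(tokens, levels = vocab))
  chi <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(chi$p.value, 1e-4)
})

test_that("topic queries render in every formulation and parse cleanly", {
  corp <- generate_corpus(generator_config(seed = 43L, n_docs = 10L))
  t1 <- names(corp$topic_concepts)[1]
  for (f in c("TXT", "CUI", "MIX", "PH-LS")) {
    qs <- topic_query(corp, t1, f)
    q <- parse_query(qs)
    expect_gt(length(q$nodes), 0L)
  }
  expect_match(topic_query(corp, t1, "CUI"), "^cui:C")
  expect_match(topic_query(corp, t1, "PH-LS"), "#l\\(cui:")
  expect_error(topic_query(corp, "nope", "TXT"), "unknown topic")
})

test_that("misconfiguration fails loudly", {
  expect_error(generator_config(n_docs = -1))
  expect_error(generate_corpus(generator_config(vocab_size = 2L,
                                                n_concepts = 10L)),
               "vocabulary smaller")
  # n_docs = 0 is a valid empty corpus
  empty <- generate_corpus(generator_config(n_docs = 0L))
  expect_length(empty$docs, 0L)
})
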