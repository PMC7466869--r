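# Fixtures built in code: the worked-example document and small random
# layered corpora used by the oracle-equivalence suites.

# The four-token obstetric example with named-entity, POS, and dependency
# layers: "pregnancy with preterm delivery".
fig_document <- function() {
  layered_document(
    "visitA",
    c("pregnancy", "with", "preterm", "delivery"),
    layers = list(
      cui = list(artifact("C0032961", 0, 1),
                 artifact("C0151526", 2, 2),
                 artifact("C0011209", 3, 1)),
      pos = list(artifact("NN", 0), artifact("IN", 1),
                 artifact("JJ", 2), artifact("NN", 3))
    ),
    relations = list(
      dep = list(relation_artifact("prep_with", span(0, 1), span(3, 1)))
    )
  )
}

# A dense random layered corpus for oracle equivalence: few distinct
# values so term/phrase/relation matches are frequent. Independent of the
# synthetic_data generator (which is itself under test).
random_layered_corpus <- function(seed, n_docs = NULL, max_tokens = 30L) {
  set.seed(seed)
  if (is.null(n_docs)) n_docs <- sample(3:8, 1)
  alphabet <- c("alpha", "beta", "gamma", "delta", "eps")
  cuis <- c("C1", "C2", "C3")
  labels <- c("nsubj", "dobj")
  lapply(seq_len(n_docs), function(d) {
    n <- sample(5:max_tokens, 1)
    tokens <- sample(alphabet, n, replace = TRUE)
    n_art <- sample(0:6, 1)
    cui_df <- if (n_art > 0) {
      starts <- sample(seq_len(n) - 1L, n_art, replace = TRUE)
      lens <- pmin(sample(1:2, n_art, replace = TRUE), n - starts)
      data.frame(value = sample(cuis, n_art, replace = TRUE),
                 start = starts, length = lens, stringsAsFactors = FALSE)
    } else NULL
    n_rel <- sample(0:4, 1)
    rel_df <- if (n_rel > 0 && n >= 2) {
      s <- sample(seq_len(n) - 1L, n_rel, replace = TRUE)
      t <- sample(seq_len(n) - 1L, n_rel, replace = TRUE)
      data.frame(value = sample(labels, n_rel, replace = TRUE),
                 src_start = s, src_len = 1L,
                 tgt_start = t, tgt_len = 1L, stringsAsFactors = FALSE)
    } else NULL
    layers <- list()
    if (!is.null(cui_df)) layers$cui <- cui_df
    relations <- list()
    if (!is.null(rel_df)) relations$dep <- rel_df
    layered_document(sprintf("d%02d", d), tokens, layers = layers,
                     relations = relations)
  })
}

new_query_for_test <- function(nodes) layerlm:::new_query(nodes)

# Random query ASTs for parse/render round-trip property tests.
random_ast_node <- function(depth = 0L) {
  layers <- c("text", "cui", "pos")
  values <- c("alpha", "beta", "C0019158", "NN", "x1")
  rand_term <- function() {
    term_node(sample(layers, 1), sample(values, 1))
  }
  rand_list <- function() {
    list_node(lapply(seq_len(sample(1:3, 1)), function(i) rand_term()))
  }
  type <- sample(c("term", "list", "phrase", "relation"), 1,
                 prob = c(0.4, 0.2, 0.25, 0.15))
  node <- switch(type,
    term = rand_term(),
    list = rand_list(),
    phrase = {
      comps <- lapply(seq_len(sample(2:4, 1)), function(i) {
        if (stats::runif(1) < 0.3) rand_list() else rand_term()
      })
      phrase_node(sample(1:20, 1), stats::runif(1) < 0.5, comps)
    },
    relation = {
      pat <- function() if (stats::runif(1) < 0.4) "*" else rand_term()
      relation_node("dep", sample(c("*", "nsubj"), 1), pat(), pat())
    })
  if (stats::runif(1) < 0.5) {
    node$weight <- sample(c(0.05, 0.1, 0.85, 2, 0.5), 1)
  }
  node
}
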