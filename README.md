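# layerlm

Ranked retrieval over **aligned annotation layers**: documents that carry,
besides their token sequence, the output of an NLP pipeline — lemmas,
part-of-speech tags, UMLS-style concept identifiers (CUIs), semantic types
(TUIs), dependency-parse edges — all aligned to the base tokens by spans
`(start, length)`. The package is aimed at search problems such as patient
cohort identification in clinical notes, where a query may need to mix
coarse free-text evidence with fine-grained semantic structure ("a
dependency edge whose head lemmatizes to *give* and whose dependent is a
proper noun").

## The model

Documents and queries are sequences of layers `L_0, L_1, ...` over a base
token layer `L_0 = L_text`. Every artifact in a non-base layer records a
span in base-token coordinates; relation artifacts record two spans
(source and target). Scoring is query likelihood with Dirichlet smoothing,
evaluated **within each artifact's own layer** `a`:

    P(t | D) = (#t_D + mu * #t_C / |C|_a) / (|D|_a + mu)

where `#t_D` / `#t_C` are document / collection occurrence counts, `|D|_a`
/ `|C|_a` the document / collection sizes of layer `a`, and `mu` the
Dirichlet pseudo-count (default 2000). Cross-layer **phrase queries**
`#p(w|o|c1|c2|...)` count tuples of artifacts, one per component and from
any layers, whose base spans fall within a window of `w` tokens (measured
from the end of the earliest artifact to the start of every other; ordered
phrases must additionally be sequential and non-overlapping). The phrase
estimate reuses the same smoothing form with the size of the **largest
stipulated layer** in the denominator. **List queries** `#l(x|y)` score
members independently and act as disjunctive matchers inside phrases;
**relation queries** `#r(layer|SRC|TGT)` count labelled edges whose
endpoints overlap artifacts matching the patterns. A document's score is
the weighted sum of log node probabilities, and the classical bag-of-words
query-likelihood model is recovered exactly by text-layer term queries.

Sequential-dependence (Markov random field) expansion rewrites an atom
sequence into unigrams (weight 0.85) plus ordered (0.1) and unordered
(0.05) phrases over every contiguous subsequence of up to 5 atoms, with
window `4k` for `k` components:

```r
> render_query(sdm_expand("cui:C0019196 cui:C0019158"))
cui:C0019196^0.85 cui:C0019158^0.85 #p(8|true|cui:C0019196|cui:C0019158)^0.1 #p(8|false|cui:C0019196|cui:C0019158)^0.05
```

## Worked example

A four-token note fragment, "pregnancy with preterm delivery", carries a
named-entity layer in which the concept C0151526 spans tokens 2–3, and a
dependency edge from token 0 to token 3:

```r
library(layerlm)
doc <- layered_document(
  "visitA", c("pregnancy", "with", "preterm", "delivery"),
  layers = list(cui = list(artifact("C0032961", 0, 1),
                           artifact("C0151526", 2, 2),
                           artifact("C0011209", 3, 1))),
  relations = list(dep = list(relation_artifact("prep_with",
                                                span(0, 1), span(3, 1)))))
idx <- build_index(list(doc))
cfg <- smoothing_config(mu = 10)
score_term(idx, term_node("cui", "C0151526"), "visitA", cfg)
#> [1] 0.3333333    # (1 + 10 * 1/3) / (3 + 10): 1 of 3 concept artifacts
ph <- parse_query("#p(8|true|preterm|delivery)")$nodes[[1]]
score_phrase(idx, ph, "visitA", cfg)
#> [1] 0.25         # (1 + 10 * 1/4) / (4 + 10): 1 ordered match, 4 tokens
```

End to end on a synthetic corpus (60 documents, 6 topics, concepts planted
into relevant documents), comparing a text MRF run against a concept-only
bag-of-words run:

```r
corp <- generate_corpus(generator_config(seed = 42, n_docs = 60))
tq   <- generate_topics_and_qrels(corp)
idx  <- build_index(corp$docs)
res  <- lapply(tq$topics$topic_id, function(t)
  rank_documents(idx, sdm_expand(topic_query(corp, t, "TXT")), k = 60))
names(res) <- tq$topics$topic_id
evaluate_run(res, tq$qrels)
#> MAP 0.8767 over 5 topic(s) (1 skipped, no relevant docs)
```

(The CUI-BOW formulation of the same topics gives MAP 0.8432 on this
corpus.) The MAP is the mean over topics of average precision, i.e. of the
mean precision at each relevant document's rank; the skipped topic drew no
planted documents at this planting rate and is excluded rather than
zero-scored.

## Command line

```sh
inst/cli/layerlm simulate --seed 42 --out-docs docs.jsonl \
    --out-topics topics.tsv --out-qrels qrels.txt
inst/cli/layerlm index --input docs.jsonl --output index.json
inst/cli/layerlm expand --query "coinfected hepatitis c hiv" --sdm
inst/cli/layerlm search --index index.json --query "cui:C0019158 hiv" \
    --mu 2000 --k 1000 --output run.txt
inst/cli/layerlm eval --run run.txt --qrels qrels.txt --per-topic
inst/cli/layerlm experiment --docs docs.jsonl --topics topics.tsv \
    --qrels qrels.txt --run run.txt --formulation TXT-MRF
```

## Layout

- `R/` — layer model, JSONL/TREC IO, positional index, query language and
  SDM expansion, scoring engine, synthetic generator, evaluation, CLI.
- `tests/testthat/` — unit, property, and oracle-equivalence suites plus
  the acceptance criteria (`test-acceptance.R`); the brute-force oracle in
  `helper-oracle.R` never touches the index.
- `vignettes/aligned-layer-retrieval.Rmd` — the methods vignette: model,
  counting semantics, smoothing choices, generator design, limitations.
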