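---
title: "Aligned-layer retrieval: model, counting semantics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligned-layer retrieval: model, counting semantics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerlm)
```

## The representation

A layered document is a base token sequence (`L_text`) plus named artifact
layers and relation layers. Every artifact carries a value (a lemma, POS
tag, concept identifier, ...) and a span `(start, length)` in 0-based
base-token coordinates, with exclusive end `start + length`. Relation
artifacts carry a label and two spans (source and target); they reference
*positions*, never artifacts in other layers, so the representation is
deliberately slightly lossy: a dependency edge survives as geometry even
after the parse tree that produced it is gone. Overlapping and duplicate
artifacts within a layer are legal and each counts separately in layer
sizes — clinical NER routinely emits several concepts over one span.

Stopwords are **never** removed from stored token sequences: removing
tokens would shift every recorded span. Stopping is a scoring-vocabulary
concern: query-side text terms that are stopwords are dropped
(`drop_stopword_terms`), and the text-layer size used in denominators can
optionally exclude stopwords (`use_stopped_text_sizes`, default off — the
all-token size is used, since nothing in the source material pins this
down and keeping spans authoritative takes priority).

## Term scoring

Term queries are scored by query likelihood with Dirichlet smoothing,
entirely within the term's own layer $a$:

$$P(t \mid D) = \frac{\#t_D + \mu \,\#t_C / |\mathbf{C}|_a}{|D|_a + \mu}$$

Per layer and document this is a proper distribution over the layer's
collection vocabulary (the package asserts $\sum_t P(t\mid D) = 1$ to
1e-9), so the classical text-only query-likelihood model is exactly the
special case of term queries on `L_text`. Terms with no collection
evidence score 0 and are *skipped* in document scores rather than floored:
a floor constant would distort comparisons between query formulations and
no principled value presents itself. $\mu$ defaults to 2000, the
conventional setting for query likelihood; it is overridable globally and
per layer (concept layers are an order of magnitude sparser than text, so
a smaller $\mu$ can be appropriate there).

As $\mu \to 0$ the estimate tends to the maximum-likelihood
$\#t_D/|D|_a$; as $\mu \to \infty$ it collapses to the collection
proportion and ranking degenerates. Both limits are asserted in the test
suite.

## Phrase counting semantics

A phrase `#p(w|o|c1|...|ck)` counts artifact tuples $(a_1,\dots,a_k)$,
$a_i$ matching component $i$, under a window measured in base-token
positions. Let $f$ be the tuple member with minimal start (ties broken by
minimal end). The window constraint is

$$\text{start}(a_i) \le \text{end}(f) + w \quad\text{for all } i,$$

i.e. from the end of the earliest artifact to the start of every other;
the last artifact may *end* outside the window. Ordered phrases
additionally require sequential, non-overlapping artifacts in component
order ($\text{start}(a_{i+1}) \ge \text{end}(a_i)$), which makes the first
component the earliest artifact, so the window reduces to
$\text{start}(a_k) - \text{end}(a_1) \le w$.

Two consequences of this definition are worth making explicit:

- **All qualifying tuples are counted**, including overlapping ones.
  Greedy position-consuming alternatives exist but are
  order-of-enumeration dependent; tuple counting is the only definition
  that admits an unambiguous brute-force oracle, which the test suite
  exploits (an independent enumerate-and-filter implementation must agree
  on every count to 1e-9 across hundreds of random corpora).
- **Unordered tuples may reuse one artifact in several slots** (e.g. the
  components both match the same token). Nothing in the stated rules
  excludes this, and the ordered variant's non-overlap requirement is the
  only stated exclusion. Counts are therefore an upper bound on "distinct
  co-occurrences" when components overlap in vocabulary.

The phrase estimate replaces term counts with match counts and uses the
size of the **largest layer stipulated in the phrase** in both denominator
positions — a backed-off estimate answering "of the artifacts in the
biggest layer involved, what fraction participates in a consistent
phrase?". The sparse alternative (product of layer sizes) is available via
`smoothing_config(phrase_denominator = "product")` but is neither default
nor validated against any reference behaviour. Collection-wide phrase
counts are not precomputed (the phrase vocabulary is unbounded); they are
evaluated lazily over the collection and memoized per phrase on the index.

Lists score standalone as their members scored independently (a product of
probabilities, i.e. a sum of weighted logs), and act inside phrases as
disjunctive matchers: an artifact matches a list if it matches any member.
Duplicate members are deduplicated by (layer, value) when matching, so a
degenerate list cannot double-count an artifact.

Relation queries `#r(layer|SRC|TGT)` count edges whose label matches and
whose source/target spans overlap (token-range intersection) some artifact
matching the corresponding pattern; `*` matches unconditionally. The count
feeds the term formula with the relation layer's own sizes. This supports
back-off queries when entity recognition fails — e.g. an edge whose head
lemmatizes to *give* with a proper-noun dependent, standing in for an
undetected medication mention.

## Sequential-dependence expansion

`sdm_expand()` keeps each atom at weight 0.85 and adds, for every
contiguous subsequence of $k$ atoms ($2 \le k \le 5$), an ordered phrase at
weight 0.1 and an unordered phrase at weight 0.05, both with window $4k$.
The per-component window constant 4 is inferred from the canonical windows
(8/12/16 for $k = 2/3/4$) and exposed as `window_per_component`; the cap
of 5 is read as a cap on phrase *length*, not on query length — longer
queries still expand fully, but no phrase exceeds 5 components, the only
reading consistent with a four-term query expanding through its 4-gram.
Lists are legal atoms and inherit term window semantics (a list matches
where any member matches); weights attach only to top-level nodes, so a
list inside a phrase contributes no weight of its own.

## Ranking and evaluation

Document scores are $\sum_i w_i \log P(\text{node}_i \mid D)$ with a
uniform document prior dropped; ties break by ascending document id so
runs are reproducible byte for byte. Evaluation is binary-relevance
average precision normalized by the total number of relevant documents
(trec_eval convention), with topics lacking relevant documents skipped,
not zero-scored, and judged topics missing from a run scored 0.

## The synthetic world

`generate_corpus()` emulates the *statistical shape* of clinical NLP
pipeline output, not its content: base tokens from a Zipf unigram model
over a pronounceable pseudo-vocabulary; a concept dictionary of 1–3-token
surface forms with unique CUIs mapped many-to-one onto TUIs; longest-match
left-to-right dictionary tagging (so multi-word concepts yield spans with
length > 1, and overlapping entries both fire); token-aligned lemma
(plural-s stripping over a ~10% pluralization rate) and POS layers; and
per-sentence uniformly random dependency trees (Prüfer decoding — no
linguistic realism claimed; the layer exists to exercise relation
queries). Defaults — 60 documents of 40–80 tokens, 150-word vocabulary, 12
concepts, 6 topics of 2 concepts, planting rate 0.2 with 2 insertions per
concept — were chosen once as a desk-scale stand-in for a visit collection
in which a topic's concepts occur repeatedly in relevant visits and
sporadically elsewhere (background documents receive a distractor concept
half the time).

Relevance is the planted topic assignment recorded at generation, never
re-derived by retrieval, so qrels are retrieval-independent. Each topic
also carries one non-concept *context* token inserted into its planted
documents: it keeps the formulations honestly distinct (entity-only CUI
queries drop it; TXT/MIX/PH-LS keep it), mirroring how free-text words
around named entities survive concept rewriting.

What a green test on this world establishes: the machinery — alignment,
counting, smoothing, expansion, ranking, evaluation — is internally
consistent and matches an independent brute-force oracle. What it does not
establish: retrieval quality on clinical text, which depends on
negation/family-history semantics, report structure, and concept-mapper
behaviour that the generator deliberately does not model. Headline MAP
figures on the restricted patient-visit collection are consequently out of
reach and out of scope here.

## Numerical and degenerate-input choices

- All scoring is done in the log domain at combination time only;
  individual probabilities are exact rational expressions in double
  precision, and oracle equivalence is asserted at 1e-9.
- Zero-evidence nodes (no collection occurrences) are skipped with an
  optional message, never scored $-\infty$; an all-out-of-vocabulary query
  scores every document 0 and ranking falls back to document-id order.
- An empty layer collection-wide scores 0 with a warning rather than
  erroring: a query may legitimately reference a layer that an individual
  corpus happens not to populate.
- Empty documents, empty corpora, and zero-document generator configs are
  all valid and round-trip through IO and indexing.
- Weight rendering uses up to 15 significant digits without scientific
  notation, which keeps parse∘render an exact identity for the weight
  grids used in practice.

## Known limitations

- Phrase counting enumerates candidate tuples per document; with
  pathological corpora (a single value filling a long document, 5-way
  phrases) the ordered counter's pruning keeps this tractable but the
  unordered counter is quadratic in candidate count per slot pair. Fine at
  collection sizes this package targets; an engine-grade implementation
  would add positional skip lists.
- The index is in-memory with JSON serialization; no compression,
  sharding, or incremental updates.
- Character-offset alignment is out of scope by design: layers align on
  tokens, and the tokenizer is a deliberately simple
  whitespace-and-punctuation rule (the upstream pipeline's tokenizer is
  not reproduced).
- Query formulation research — weight learning, expansion from logs,
  automatic concept rewriting of raw topic text — is out of scope; the
  experiment driver accepts pre-rewritten query strings per formulation.
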