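---
title: "Context-aware concept normalization: model, parameters, and design notes"
author: "ontoNorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware concept normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoNorm)
```

## The problem

Concept recognition in biomedical text has two sequential stages. *Named
entity recognition* finds the character spans of entity mentions; *named
entity normalization* links each span to an identifier in a knowledgebase
(for Gene Ontology biological-process terms, a `GO:` id). Dictionary lookup
handles short, stable names well, but multi-token terms vary enormously in
running text — reorderings, insertions, and paraphrases that no finite
synonym list covers. ontoNorm addresses the normalization stage by scoring
candidates with *contextual evidence from the ontology itself*: not just the
concept's name, but its definition and the names of its `is_a`/`part_of`
parents.

## The model

For a mention $m$ and a candidate entry $c$ (a concept's primary name or one
of its synonyms), both are mapped to vectors by a sentence-embedding backend
and compared by cosine similarity. Five similarities form the feature vector

$$x(m, c) = \big(\cos(m, c_\text{name}),\ \cos(m, c_\text{def}),\
\cos(m, c_{h_1}),\ \cos(m, c_{h_2}),\ \cos(m, c_{h_3})\big),$$

where $c_{h_1..h_3}$ are up to three hierarchical contexts — the primary
names of the concept's direct parents, `is_a` parents first, then `part_of`,
in stanza order — and missing slots contribute similarity 0. Two scoring
strategies rank candidates:

* **cosine** — the unweighted sum $\sum_j x_j$; no training required.
* **regression** — a ridge-penalized logistic regression fitted to gold
  mention–concept pairs (positives) against sampled negatives; candidates
  are ranked by the linear predictor $w^\top x + b$.

Every synonym is expanded into its own entry sharing the concept's
definition and contexts; after scoring, entries collapse back to concepts by
the best-scoring entry, so a synonym match predicts its concept. Ties are
broken by ascending concept id everywhere, making rankings deterministic.

## Assumptions and contracts

* **The tagger is a contract, not a model.** Anything that maps text to
  spans can feed the normalizer. The package ships a gazetteer baseline
  (case-insensitive leftmost-longest match over entry surfaces at token
  boundaries) so the full pipeline runs without any trained tagger; a neural
  BIO tagger plugs in through the same annotation data.frame. The BIO codec
  (`encodeBIO`/`decodeBIO`) repairs orphan `I` labels by treating them as
  `B`, since real taggers emit illegal sequences and dropping them would
  silently lose recall.
* **The embedding backend is a contract too.** `mockEmbedding()` is a
  deterministic hashed character-trigram bag (lower-cased, `##`-padded,
  L2-normalized; default 512 buckets). It preserves the one property the
  pipeline needs — similar surfaces get high cosine — with no downloads and
  exact reproducibility. A pretrained sentence-transformer can be wrapped as
  another `EmbeddingBackend` subclass for real corpora; trigram bags see
  only the surface, not meaning, so paraphrases that share no substrings
  (e.g. "formation" vs "assembly") score 0 here but would score high under a
  neural backend.
* **Mentions are embedded as their own string**, without surrounding
  sentence context. Definitions may be empty; empty text embeds to the zero
  vector and any cosine with it is defined as 0 (neutral evidence).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` (context slots) | 3 | direct-parent names used as hierarchical evidence; slots, not ancestor levels |
| `dim` (mock backend) | 512 | trigram hash buckets |
| `negativesPerPositive` | 10 | negatives sampled uniformly from non-gold concepts per gold pair, seeded |
| `lambda` | 1e-3 | ridge penalty; weak on purpose — it stabilizes separable data without materially shrinking coefficients |
| `topN` | all | candidate prefilter by surface similarity; exhaustive scoring is the default because candidate selection is not part of the model |

Interpreting "up to 3 hierarchical contexts" as three *parent slots* (rather
than three ancestor levels) keeps the context local and the feature vector
fixed-length; only direct parents are used.

## Evaluation

Predictions and references are aligned per document: exact agreements on
(start, end, concept id) are correct slots `C` — these pairs are unique
because spans within one list cannot overlap — and the remaining annotations
are paired one-to-one wherever spans overlap by at least one character,
using a maximum-cardinality bipartite matching (via igraph), giving
substitutions `S`. Unpaired predictions are insertions `I`; unpaired
references are deletions `D`. The counts are identical across all maximum
matchings, so the procedure is deterministic, and it provably minimizes the
total slot error for the fixed `C`; a greedy largest-overlap-first pairing
was rejected because a prediction spanning two references can block a
two-pair matching and overcount errors. Reported measures are the Slot
Error Rate $\mathrm{SER} = (S+D+I)/(C+S+D)$ and exact-span
precision/recall/F1, micro-averaged by summing counts across documents.
Boundary mismatch with a correct id counts as a substitution, never as
correct. Equivalence with any particular external scorer implementation is
not claimed.

## What the synthetic fixtures emulate — and what they do not

`generateOntology()`/`generateCorpus()` produce a download-free, seeded
study condition: an acyclic ontology whose multi-token names appear in text
under controlled variation (verbatim, synonym substitution, interior token
shuffling, stop-word insertion), emulating how longer biological terms vary
in literature. The generator is designed so that a controlled recovery
experiment is actually controlled — the gold standard is uniquely
resolvable:

* mentions are drawn from *leaf* concepts: a non-leaf's name is, verbatim,
  the hierarchical-context string of each of its children, so a mention of
  it is exactly ambiguous for any scorer weighting all features equally;
* names are 3–4 words from a 50-word pool of 6–11-character words, and no
  two concepts share more than one content word — similarity structure is
  informative without near-duplicate names (the trigram backend would let a
  single very long or very short shared word dominate otherwise);
* definitions restate the name plus two distractor words, so definition
  similarity tracks the denoted concept;
* every non-root takes the same number of parents and shares exactly one
  name word with its primary parent, the way a GO child ("blood
  coagulation") shares a head word with a parent ("coagulation") — this is
  what makes the concept's own hierarchy slot informative evidence;
* connective prose between mentions uses a vocabulary disjoint from the
  concept word pool, so dictionary matches cannot cross mention boundaries.

Under these conditions the no-variation ceiling holds: with identity-only
variation the gazetteer plus the untrained cosine strategy reach exact-span
F1 of 1.0, and this was verified across 150 generator seeds. What passing
these tests does **not** show: performance on real corpora, where mention
variation is semantic rather than combinatorial, annotation spans are
noisier, concept inventories are orders of magnitude larger, and a trigram
backend is no substitute for a trained sentence embedder. The fixture
measures the *machinery* — span decoding, feature construction, ranking,
alignment — not biomedical state of the art. `token_shuffle` permutes
interior tokens only, so it perturbs only 4-word names; surface variation
for 3-word names comes from synonym substitution and filler insertion.

Default condition sizes (30 concepts, 10 evaluation documents of 5 mentions,
a 20-document training corpus, 10 negatives per positive) keep the full
benchmark under a few seconds while leaving every measured rate supported by
50 gold mentions.

## Numerical choices and degenerate inputs

* Character offsets are 0-based half-open throughout (brat convention).
* Ranking ties break by ascending concept id; candidate-cutoff ties
  likewise.
* The regression fit is deterministic: fixed ridge path, no random
  initialization; training-set assembly seeds its negative sampler and
  restores the caller's RNG state.
* Degenerate inputs have defined behavior: empty OBO streams parse to empty
  graphs; an empty candidate index yields an empty ranking; SER on an empty
  reference is an error, not 0; a single-class training set under the
  regression strategy is an error.
* Obsolete concepts stay in the graph (they may be parents) but are never
  normalization entries.

## Known limitations

The model always returns a nearest concept — there is no NIL threshold, so
precision on corpora with out-of-ontology mentions must be managed
upstream. Discontinuous spans, multi-type BIO tagging, and OBO constructs
beyond `id`/`name`/`def`/`synonym`/`is_a`/`relationship: part_of` are out of
scope. The regression ranker is pairwise-pointwise (binary labels per
mention–candidate pair), not a listwise ranking objective.

## A worked example

```{r example}
g <- parseOBO(system.file("extdata", "blood_coagulation.obo",
                          package = "ontoNorm"))
entries <- expandEntries(g)
idx <- buildConceptIndex(entries, mockEmbedding())
doc <- "In these patients, blood clotting was impaired within minutes."
spans <- gazetteerTag(doc, entries)
normalizeAnnotations(spans, fitRanker(strategy = "cosine"), idx)
```

```{r benchmark}
bm <- fixtureBenchmark(fixtureParams())
c(regression_ser = bm$metrics$regression$ser,
  regression_f1 = bm$metrics$regression$f1,
  top1 = bm$top1Accuracy[["regression"]])
```
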