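---
title: "Entity-centric ranking: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entity-centric ranking: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrank)
```

## The problem and the approach

Document search engines answer a biomedical question with a reading list.
`entrank` instead treats the *entity* as the unit of retrieval: at indexing
time every abstract-like document is tagged with the biomedical entities it
mentions, and each document is stored as a paired posting — its id plus its
entity list — under every token it contains. At query time the engine
retrieves matching postings, scores each document, and sums document scores
per entity, so the answer to "chronic myeloid leukemia" is a ranked list of
drugs, genes and mutations rather than a pile of abstracts.

The pipeline has five stages, each an exported surface you can use alone:
dictionary construction (`merge_records()`), mention extraction
(`extract_entities()`, `extract_mutations()`), indexing
(`entity_index()`, `add_documents()`), query parsing (`parse_query()`) and
scoring (`search_entities()`), plus evaluation helpers (`prf1()`,
`precision_at_k()`).

## Dictionary construction

Entity names come from multi-source records `(source, surface, type,
xrefs)`. Two records sharing any cross-reference identifier are synonyms
and merge transitively into one concept; records with the same case-folded
surface in the same priority group also merge. Types live in four priority
groups — gene (genes/proteins, targets, transcription factors, miRNAs),
chemical (compounds, drugs, toxins), disease, pathway — and a concept may
hold several types *within* one group but never across groups. When merging
drags in types from several groups the highest-priority group wins
(gene > chem > disease > pathway) and losing types are pruned; this guards
against occasional mislabeled source records.

Where the original curation workflow used human reviewers to clean the
merged dictionary, this package substitutes a configurable exclusion list
(`stop_surfaces`), which is the only automatable equivalent.

Three decisions here were genuinely open and are fixed as follows:

* **Concept identifiers.** Concepts are sorted by (group priority, smallest
  case-folded name) and numbered `C00001…`; ids are therefore stable under
  record permutation, which makes index builds reproducible.
* **Ambiguous surfaces.** A surface that survives merging in more than one
  concept is mapped, at build time, to the concept of the highest-priority
  group, ties to the smallest concept id. Retrieval never has to
  disambiguate at query time.
* **Case sensitivity.** Matching is case-insensitive, except surfaces that
  are all-uppercase and at most 4 characters (gene-symbol shape: `CD4`,
  `ABL`) match case-sensitively, because such strings collide with ordinary
  words far too often.

## Mention extraction

Tagging is token-based: tokens are maximal alphanumeric runs with internal
hyphens kept (`BCR-ABL` is one token), and a surface matches only a run of
whole consecutive tokens, so `HER` can never fire inside `OTHER`. At every
position the longest dictionary match wins and overlapping shorter matches
are suppressed; the scan is greedy left to right, which equals the
enumerate-then-select oracle used in the tests.

Mutation mentions are a deliberately simple pattern pair rather than a
learned model: protein point mutations `[A-Z][0-9]+[A-Z]` (T315I, Y253H)
and coding changes `c\.[0-9]+[ACGT]>[ACGT]`, both on word boundaries. Each
normalized surface becomes its own concept (`MUT:T315I`) in a separate
mutation group. This keeps genetic-variant retrieval exercisable end to end
while making no claim to the coverage of a full variant tagger (no protein
three-letter codes, no frame-shifts, no rs-ids).

## The index

The index stores the document table, one posting per document, a
`(term, doc, tf)` table and the dictionary. Tokenization for indexing is
the same tokenizer, lowercased, with no stemming — stemming is deliberately
absent so that term statistics remain exactly reconstructible. Stop words
**are** indexed; they are removed only from queries. Incremental
`add_documents()` batches are required (and tested) to produce an index
identical to a single scratch build, so daily-addition style updates need
no rebuild. Deleting or replacing documents is unsupported; corrections go
through a rebuild.

## Query language

`parse_query()` supports `AND`/`OR`/`NOT` (also `+`/`-` prefixes),
parenthesized groups, quoted phrases, per-element boosts (`imatinib^3`)
and an inclusive year filter (`year:[1990 TO 2005]`, `*` for an open end;
em/en dashes accepted). Stop words come from a built-in 33-word list,
overridable per call.

The implicit operator between bare terms is **OR**: a document matching any
positive element is a retrieval candidate. This is the semantics consistent
with the coordination factor, whose lower bound of 1/|q| only matters if
partially matching documents are retained; demanding all terms would make
`coord` constant at 1. Unquoted multi-word disease names are therefore
bags of terms, not phrases — quote them to force adjacency. A phrase counts
as a single query element for `coord`, matches exact consecutive token
runs, and `NOT` clauses affect retrieval only, never scoring.

## Scoring

A matching, entity-bearing document scores
`S_d = T_d^a · N_d^b · Q_d^c · R_d^p`, and an entity sums `S_d` over its
matching documents. Component details and the parameters that matter:

* **Term match** `T_d = coord · tfidf`. The TF-IDF dialect is fixed to
  `boost · √tf · (1 + ln(N/(df+1)))²` per matched element — the classic
  similarity of Lucene-family engines, which is the retrieval stack this
  design descends from. Query-norm and length-norm are omitted: they
  rescale all candidates of a query equally or depend on engine-specific
  field statistics, and leaving them out keeps scores exactly reproducible
  from the corpus statistics alone. Phrase `tf`/`df` are counted by
  scanning the documents that contain all constituent tokens.
* **Entity number** `N_d = 1/min(|E_d|, 10)`, in [0.1, 1]: a document
  mentioning one entity is strong evidence for it; a 25-entity survey
  paragraph is weak evidence for each.
* **Reputation** `Q_d = 1 + IF_d/max(IF)·9`, in [1, 10]; no or zero impact
  factor gives 1, so unranked journals are never penalized below the floor.
* **Recency** `R_d = (1/2)^(min(M−m_d, 96)/24)`, halving every 24 months,
  floored at 0.0625 beyond 8 years. The reference month `M` defaults to the
  newest publication month in the corpus and is overridable (`as_of`), so
  scoring is reproducible offline instead of depending on the wall clock.
  Documents with no publication date are kept but scored at the floor (and
  flagged on ingestion) — exclusion would silently change `df` statistics.
* **Powers** `a, b, c, p` (`score_weights()`) default to 1, reproducing the
  plain product; 0 disables a component, and the package applies powers to
  all four components uniformly even though only the recency power is
  commonly tuned — there is no reason to privilege one component in the
  API.

Ties are broken by contributing-document count, then concept id;
aggregation is the plain sum over `D_e` with no per-entity cap or
normalization by |D_e| — the plain sum is the defining form of the method, and any dampening
is better done transparently via the powers.

## Synthetic fixtures

`generate_fixture()` builds corpora in which the ground truth is exact by
construction: filler vocabulary and entity surfaces are disjoint token
sets, so every planted mention is recoverable and extraction on such a
corpus must reach precision = recall = 1. Concepts get 1–3 synonyms
(occasionally two-token, to exercise longest-match), a shared xref per
concept (exercising synonym merging), uniform impact factors on
[0, `max_if`] with a configurable missing fraction, and uniform publication
dates over a year range. A planted "topic" token co-occurs with designated
relevant concepts at a high rate (default 30% of documents) against a 5%
background, so ranked retrieval must recover them. Defaults (100 documents,
22 concepts over the four groups, ~2 mentions/document) are sized like a
focused abstract subcollection while keeping every test's brute-force
oracle affordable.

`cohort_fixture()` builds the recency experiment: an old cohort (age 100
months, past the 96-month cap) and a new cohort (age 0) with identical
sizes, identical text statistics and no impact factors, so the two planted
concepts tie exactly when the recency power is 0 and separate by
`(R_new/R_old)^p` otherwise — a closed form the tests check literally.

What the fixtures do **not** emulate: natural language (no grammar, no
abbreviations, no punctuation variety), surface ambiguity across concepts,
entity mentions inside hyphenated compounds, skewed document-frequency
distributions, or realistic journal/impact-factor correlations. Passing
tests therefore certify the mechanics of merging, tagging, indexing and
scoring — not extraction quality on real prose, which depends on dictionary
coverage.

## Numerical and testing choices

Scores are plain double-precision products of bounded factors; the only
tolerance in the suite is 1e-9 on oracle-vs-engine score equality (order is
compared exactly, after the deterministic tie-break). Test corpora run at
20–200 documents — the oracle re-scores every document-entity pair by brute
force, and 200 documents keeps that oracle exact and the full suite around
a minute. Acceptance probes read their values off the live per-document
breakdown of an indexed corpus rather than calling the component functions
in isolation, so they also exercise date handling and corpus statistics.

## Known limitations

* Dictionary tagging has no abbreviation resolution, species
  disambiguation or machine-learned context; precision on real text rests
  on dictionary quality and the exclusion list.
* The mutation patterns are a minimal stand-in for a dedicated variant
  tagger.
* Proximity search is not implemented; phrases are the only positional
  operator.
* The index is in-memory and single-machine; persistence is line-delimited
  text chosen for inspectability, not compactness.
* Impact factors enter as supplied; the package does not source them.
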