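---
title: "Concept-based retrieval with association-mined relevance feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-based retrieval with association-mined relevance feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptrf)
```

## The retrieval model

`conceptrf` implements a concept-level relevance-feedback pipeline for
literature search. Documents are not bags of words but bags of sentences of
*concept identifiers* — the output of a concept-mapping stage such as UMLS
MetaMap, which normalises free text into CUIs. Working at the concept level
lets a "query" be arbitrarily complex (a question, a paragraph): whatever the
user typed is itself mapped to a set of concepts $Q$.

The pipeline has three stages.

**1. Initial ranking — accumulative TF-IDF.** For a query
$Q = \{c_1, \dots, c_l\}$ and document $d_i$, each query concept contributes
its TF-IDF weight and the document score is the sum

$$\mathrm{A\text{-}TF\text{-}IDF}_Q^{d_i} \;=\; \sum_{c \in Q}
  \frac{f_{c}^{d_i}}{\sum_j f_{c_j}^{d_i}} \cdot
  \log_{10}\frac{|D|}{\mathrm{DF}_{c}},$$

where $f_c^{d_i}$ counts occurrences over the document's flattened tokens and
$\mathrm{DF}_c$ is the number of documents containing $c$.

**2. Feedback mining — weighted interest.** The user marks documents in the
top-$\chi$ window as relevant. Their sentences are pooled into a transaction
set $Z$ ($N = |Z|$ transactions), and each distinct concept $c_j$ of $Z$ forms
an association rule $Q \to \{c_j\}$ scored by the *weighted interest*

$$I^w_{c_j} \;=\; \frac{N\, f^w_{Qc_j}}{f^w_Q \, f_{c_j}},$$

a lift-style measure in which the query's per-sentence count is *fractional*
(`partial_count_query()`: the share of query concepts the sentence contains)
— multi-concept queries rarely co-occur in full within one sentence, and a
binary count would make $f_Q$ vanish. The concept count stays binary. Values
above 1 indicate association beyond the independence baseline. The top $k$
concepts form the feedback *k-profile* $P_k^Z$; the same mining applied to
each document's own sentences (with $N$ that document's sentence count)
yields per-document profiles $P_k^{d_i}$.

**3. Re-ranking — truncated rank-biased overlap.** Documents are re-ranked by
the similarity of their profile to the feedback profile,

$$\mathrm{RBO} \;=\; (1-\varphi) \sum_{d=1}^{k} \varphi^{\,d-1}
  \frac{|P_d^Z \cap P_d^{d_i}|}{d},$$

a top-weighted measure with geometric depth decay that tolerates incomplete
rankings (a prefix shorter than $d$ is compared as-is). The truncated form is
used exactly as written — no extrapolated residual — so two identical
length-$k$ profiles score the ceiling $1-\varphi^k$, not 1. Finally, selected
documents that fell out of the new top-$\chi$ window are put back by
`retain_feedback()`: walking the new window from its bottom, non-selected
documents are replaced by the missing selections, so the user never loses
what they already vetted and only the lowest-ranked newcomers make room.

```{r worked-example}
doc <- concept_document("ex1", list(
  c("1", "3", "4", "3", "5"), c("4", "5", "5", "1"),
  c("3", "5", "1", "3", "1", "6"), c("1", "5", "4", "4", "1"),
  c("5", "2", "4", "6", "2")
))
weighted_interest(doc, c("3", "2", "6"), "1")
rbo_similarity(c("2", "3", "1", "6", "8"), c("2", "1", "4", "3", "5"),
               phi = 0.9, k = 5)
```

## Parameters that matter

* **`k`** (profile depth, default 30, dimensionless): too small and
  informative co-occurring concepts are cut from the profiles; too large and
  weakly associated noise concepts dilute the overlap. The package's
  synthetic experiments reproduce this unimodal pattern (`k = 2` is
  measurably worse than `k = 30`).
* **`phi`** (RBO decay, default 0.9, in (0, 1)): the weight of depth $d$ is
  $\varphi^{d-1}$, so smaller values concentrate the comparison on the
  profile heads. 0.9 is the conventional choice, spreading non-negligible
  weight over a few tens of ranks — matched to `k` around 20–30.
* **`chi`** (review window, default 10 documents): how many top hits the user
  is willing to inspect per round; it bounds both what can be selected and
  where selections are retained.
* **`score_threshold`** (concept-mapping candidate score, default 500 on the
  0–1000 scale, strict `>`): candidates at or below the threshold are
  discarded during `parse_metamap_output()`. Raising it is monotone — it can
  only remove concepts.

## Numerical and edge-case choices

* IDF uses base-10 logarithms; ranking order is base-invariant, so the choice
  only fixes reported score values.
* A query concept absent from the corpus ($\mathrm{DF}=0$) contributes 0
  rather than an undefined value: a concept that occurs nowhere cannot
  discriminate documents.
* $f^w_Q = 0$ (query disjoint from every transaction) defines $I^w = 0$ for
  all rules — no evidence of association, and no division by zero.
* Ties are broken deterministically everywhere: rankings by ascending
  `doc_id` after descending score; profiles by descending joint frequency,
  then ascending concept token. Reruns are bit-identical.
* Empty sentences are retained as zero-count transactions; dropping them
  would silently change $N$. The line-based corpus dialect cannot encode
  them (a blank line terminates a document), so such corpora are serialised
  via the JSON-Lines dialect.
* Within one phrase occurrence, a concept reached through several
  above-threshold candidates is extracted once; a phrase occurring $m$ times
  contributes its concepts $m$ times.
* Profiles are ranked truncations with no interest floor: concepts with
  $I^w < 1$ may enter a profile if fewer than $k$ concepts beat them, mirroring
  rank-then-truncate semantics rather than hypothesis testing.
* `average_precision(..., cutoff = N)` averages precision over the relevant
  documents *retrieved within the top N* (its denominator), the convention
  that pairs naturally with reporting counts of relevant documents in the
  top 10/20. AP@N is therefore a precision-flavoured quantity; recall gains
  show up in the `rel_in_top10`/`rel_in_top20` columns.
* Each feedback round mines that round's selection only; earlier selections
  remain in the session history for audit but are not pooled into later
  transaction sets. Pooling across rounds is a plausible alternative; per-round
  mining keeps rounds comparable and was chosen for its simpler semantics.

## What the synthetic generator emulates

`generate_corpus()` builds the study conditions the package is tested under:
`n_docs = 100` documents of 5–50 sentences with 2–20 concepts each, a
vocabulary of 500 concepts with Zipf-like frequencies (exponent 1.07),
`n_relevant = 8` planted relevant documents, a 3-concept query and 5 signal
concepts, and `co_occurrence_rate = 0.6`. Three structural features make the
planted relevance learnable the way real relevance is:

* **Planted co-occurrence.** A relevant document's sentences contain, at the
  co-occurrence rate, one or more query concepts together with 1–3 signal
  concepts — the topical vocabulary shared by relevant articles that the
  query itself does not mention. One *anchor* relevant document plants the
  full query at a boosted rate, guaranteeing a relevant document with
  top-tier initial TF-IDF so feedback is reachable at all.
* **Keyword decoys.** 20% of the non-relevant documents plant query concepts
  at the same rate but carry no signal concepts: hits that match the query
  terms yet are off topic. They make the initial term-based ranking
  realistically noisy and are exactly what profile re-ranking demotes.
* **Topical coherence.** Each document writes from its own ~8%-of-vocabulary
  concept pool, so concepts recur within a document as they do in real
  articles. Without this, feedback profiles are dominated by concepts seen
  exactly once in a query-bearing sentence — singletons whose weighted
  interest is maximal but carries no information.

With `co_occurrence_rate = 0` nothing is planted and the labelled documents
are exchangeable with background: the negative control under which feedback
cannot (and in the tests does not) generalise to unselected relevant
documents.

What the generator does **not** emulate: real concept-mapping noise
(ambiguous CUIs, mapping errors), document length/vocabulary correlations,
passage-level rather than document-level relevance, and graded relevance
judgments beyond the planted binary labels. Passing the synthetic
experiments therefore shows the pipeline recovers planted co-occurrence
structure under realistic frequency and noise assumptions — not that it
attains any particular performance on a real judged collection.

## Problem sizes used in the test suite

The property tests compare the mining, ranking and overlap code against
independent brute-force oracles on 200 random feedback sets (≤ 50 sentences,
vocabulary ≤ 40) and 50-document corpora, to 1e-12. The directional
experiment simulates the top-10 feedback protocol on 25 seeded corpora of
100 documents (8 relevant, co-occurrence 0.6) and checks that mean AP@10
improves from the initial to the second-round search and that `k = 30` beats
`k = 2`; these sizes keep the full suite comfortably fast while leaving the
directional comparisons well away from noise.

## Limitations

* The truncated RBO cannot reach 1; scores are comparable across documents
  for fixed $\varphi$ and $k$ but not across different $k$.
* Weighted interest has no support floor, so very rare concepts can top a
  profile in small feedback sets; topical coherence mitigates this in
  realistic data but short, scattered feedback remains noisy.
* Binary feedback only: graded or implicit feedback is out of scope, as are
  live concept-mapping services — ingestion is file-based by design.
* `retain_feedback()` guarantees window membership for selections but can
  displace genuinely better newcomers when the user selects many documents.
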