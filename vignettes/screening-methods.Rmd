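---
title: "Seed-driven screening: model, evaluation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-driven screening: model, evaluation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenloop)
```

## The screening problem

Title/abstract screening is the most labour-intensive step of a
systematic review: a search strategy typically returns thousands to tens
of thousands of candidate articles, of which only a handful survive
full-text review. screenloop semi-automates this step with a
seed-article-driven relevance-ranking loop:

1. The review team supplies the full search result (the *corpus*) and at
   least one *seed article* — a paper known to exemplify the inclusion
   criteria.
2. Every record's title and abstract is embedded as a numeric vector,
   once per collection.
3. Unscreened records are ranked by cosine similarity to the relevant
   exemplars (seeds plus everything flagged so far) and presented in
   rounds of 50.
4. Reviewers include/exclude each presented article and may *flag* it as
   relevant; flags feed back into the ranking at the next round boundary.
5. The loop halts when the pool is exhausted or when a pre-agreed
   fraction of the pool has been screened (the evidence-based threshold).

Because relevant articles are front-loaded, most of the corpus never
needs to be read, while an exhaustive run still guarantees that every
record is presented exactly once.

## Embeddings

Two vectorizers sit behind one contract (`fit_vectorizer()` returns a
matrix with one row per record; the ranking code is agnostic to which
produced it):

* **tf-idf** — term frequency weighted by smoothed inverse document
  frequency, `idf = log((1 + N) / (1 + df)) + 1`, sublinear tf off, rows
  L2-normalized. Fully deterministic, so it is the reference ranker for
  every oracle-checked test; it is also a respectable baseline in its
  own right.
* **paragraph vectors** (distributed bag-of-words) — each document vector
  is trained by SGD with negative sampling (5 noise words per target,
  unigram^0.75 noise distribution) to predict the words it contains.
  Defaults: dimension 100, 40 epochs, minimum token count 2, learning
  rate decaying from 0.025 to 1e-4. These are conventional settings for
  abstract-length texts with this embedding family. Training is
  single-threaded over an internal deterministic RNG, so a fixed
  `train_seed` reproduces vectors bit-for-bit; the package deliberately
  trades away multi-threaded training speed for reproducibility, which
  matters more at corpus sizes where abstract screening is practical.

Text is tokenized as lowercased title + abstract with punctuation
stripped and 1-character tokens dropped. Whether to embed the title
together with the abstract is a genuine design choice; both carry
screening-relevant vocabulary, and concatenation is what a reviewer
reads, so the package embeds both. Embeddings are trained **once per
collection** and never retrained between rounds: the feedback loop
operates purely through re-ranking, which keeps rounds cheap and makes
replay results a deterministic function of (corpus, config, seed).
Records whose tokens all fall below the minimum count receive the zero
vector, score 0 against everything by convention, and therefore rank
last rather than producing NaNs.

## Ranking and the loop

A candidate's relevance is its **maximum** cosine similarity to any
relevant exemplar. Maximum (rather than mean) aggregation preserves
multi-topic seed sets: an article close to one seed is not penalised for
being far from the others. Mean aggregation is available as an option.
Excluded articles simply leave the pool; they are not used as negative
signal — the feedback the loop is defined around is positive flags only,
and down-weighting by excluded content would make results depend on the
order in which irrelevant articles happen to be screened.

Rounds are 50 articles by default. Re-ranking after every single
decision is both slower and empirically counter-productive (newly
flagged articles keep reshuffling the queue before their neighbourhood
has been explored); re-ranking only at round boundaries is the
exploration/exploitation compromise the method was designed around. Ties
in score are broken by ascending record id so that every round is
bit-reproducible. Seeds are implicit inclusions: they are never
presented and never counted as screened in any metric.

The halt threshold is interpreted against the screenable pool (corpus
minus seeds): a team with a 3600-article pool and a 50% threshold stops
after 36 rounds of 50.

## De-duplication

Duplicate removal is exact-match on the (title, abstract) pair and
deliberately conservative: only byte-identical text is removed, so
records differing by stray whitespace, punctuation or casing survive.
This costs a few residual duplicates but cannot silently drop distinct
records, and the removed/kept pairs are exported for cross-checking. An
opt-in `normalized` mode (Unicode NFC, casefolding, whitespace collapse)
approximates what a careful manual pass additionally catches; strict
removals are always a subset of normalized ones. The duplicate key is
record text rather than DOI because DOIs are frequently absent from
database exports. Record identity for re-imported files is the DOI when
present, else a content hash of the normalized title, so exported
decisions join back onto re-read corpora.

## Evaluation metrics

All replay statistics are computed from counts:

* `percent_not_reviewed(N, n_reviewed)` — the headline workload saving,
  rendered as an integer percentage (half away from zero).
* `wss_at(R, N, s)` — work saved over sampling at recall `R`:
  `(N − s)/N − (1 − R)`. At `R = 1` this coincides with
  percent-not-reviewed, a property the tests assert over a grid.
  `s` is always taken from a recall trajectory, never inferred.
* `rounds_required(n, 50)` — a ceiling count of 50-article blocks.
* `workload_savings()` / `screening_rate()` — hours into FTE days
  (7.5 h/day by default, the convention consistent with reported
  hour/FTE-day pairs) and cost at an hourly rate; currency rounds to
  whole units, days to 2 decimals, rates to 1.

Replay of a labelled corpus stops at *decision* granularity — the
decision on which the last final article is screened — and reports
rounds as `ceiling(n_reviewed / 50)`. The replayed automatic reviewer
flags at the *flagged* level, not the final level: with hindsight some
flagged articles never make the published review, but they were the
feedback signal actually available during screening, so the simulation
uses them. The `simulation_result` bookkeeping keeps seeds in their own
column: `n_reviewed + n_not_reviewed + n_seeds = N` always holds.

## The synthetic corpus family

Real review corpora are copyrighted, so the generator builds pseudo-text
stand-ins with a controllable topical signal. Decoy records draw tokens
from a shared vocabulary with Zipf weights (so idf has realistic
structure and tf-idf behaves non-trivially); relevant records draw each
token from an exclusive topic block with probability
`topic_injection_rate` and from the shared vocabulary otherwise.
Abstract lengths are Poisson around a 120-token mean with a 30-token
floor; titles are 8 tokens. Defaults — 500 records, 15 flagged, 6 final,
2000 shared words, 50 topic words, injection rate 0.5 — are a mid-sized
review with a learnable but non-trivial signal; at injection 1.0 the
flagged set is linearly separable from the decoys, at 0 the corpus is an
unlearnable null used as a sanity check.

What the generator does **not** emulate: natural-language syntax,
near-duplicate phrasing across related papers, topic drift within a
review, and the skewed relevance structure of real search results.
Passing tests on this family therefore demonstrate that the machinery is
correct and that the loop recovers a planted topical signal — not that
any particular workload saving will be achieved on a given real corpus.

## Numerical and testing choices

* Rendered percentages round half away from zero (matching how such
  tables are conventionally printed); base `round()` half-to-even is not
  used for rendering.
* tf-idf scores are checked against a by-definition brute-force oracle
  to 1e-9; round composition of the ranked loop is checked against an
  independent sort-and-step replay on corpora up to 200 records.
* Degenerate inputs: empty titles are retained with placeholders and a
  warning; punctuation-only records tokenize to empty sequences; corpora
  with fewer than 2 non-empty records refuse to train a vectorizer.
* Seed-sensitivity medians use lower interpolation on even counts so the
  summary is always an observed round count; combination sampling is
  seeded and without replacement.
* Problem sizes in the test-suite and acceptance runs (corpora of
  30–500 records, 8–20 generator seeds per property) are chosen so the
  whole suite exercises every code path at desk scale; the properties
  they check are size-independent.

## Known limitations

* Exact-match de-duplication intentionally misses near-duplicates; the
  normalized mode narrows but does not close the gap to manual cleaning.
* A final article sharing no vocabulary with any relevant exemplar ranks
  last and is only found near pool exhaustion — the exhaustive-run
  guarantee bounds the damage but cannot remove it.
* Paragraph-vector quality on very small corpora (tens of records) is
  limited; the tf-idf baseline is often the better choice there.
* Multi-reviewer support is session-file merging plus conflict
  detection; there is no shared live state.
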