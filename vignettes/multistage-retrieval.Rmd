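---
title: "Multistage retrieval for biomedical literature: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage retrieval for biomedical literature: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiret)
```

## The problem

During an infodemic — the explosive growth of publications that accompanies an
epidemic — domain experts cannot read everything, and a single ranking model is
rarely good enough to surface the relevant literature for a natural-language
information need. `multiret` implements a multistage ranking pipeline for such
collections: several cheap probabilistic rankers produce candidate lists over
an inverted index, pluggable second-stage scorers rescore the head of those
lists, and the lists are combined by reciprocal rank fusion and by a trained
logistic score-fusion model. Evaluation follows the TREC conventions for
graded relevance judgments.

An information need (a *topic*) carries three free-text fields of increasing
verbosity — `query`, `question`, `narrative` — and a document carries a title,
an abstract, an optional full text, and a publication date.

## First-stage models

Text is normalized identically at indexing and search time: lower-casing,
removal of every character outside `[a-z0-9-]`, and Porter stemming
(the classic 1980 algorithm, implemented in this package; tokens containing
digits or hyphens, such as `sars-cov-2`, pass through unchanged). No stopword
removal is applied. A small editable synonym table (shipped in
`inst/extdata/synonyms.txt`) is applied to *queries only*, appending each
synonym once after its trigger term.

Three weighting models score a term $t$ in document $d$ of collection $D$,
with $f(t,d)$ the term frequency, $|d|$ the document length, $avg_l$ the mean
length, $n_t$ the document frequency and $cf$ the collection frequency:

* **BM25** — $w = \mathrm{idf}(t)\cdot\frac{f(t,d)\,(k_1+1)}{f(t,d) + k_1(1-b+b\,|d|/avg_l)}$
  with the nonnegative Lucene-style
  $\mathrm{idf} = \ln\!\big(1 + \frac{|D|-n_t+0.5}{n_t+0.5}\big)$.
  `k1` (term-frequency saturation, default 1.2) and `b` (length
  normalization in $[0,1]$, default 0.75) are the untuned defaults used when
  no judgments exist yet.
* **DFR** — divergence from randomness with a geometric (Bose–Einstein)
  randomness model by default: with $\lambda = cf/|D|$ and the length-
  normalized frequency $tfn = f(t,d)\log_2(1+avg_l/|d|)$,
  $w = k\big[\log_2(1+\lambda) + tfn\,\log_2\frac{1+\lambda}{\lambda}\big]$.
  A Poisson randomness model is available as a configuration choice.
* **LMD** — Dirichlet-smoothed query likelihood,
  $w = \ln\frac{f(t,d)+\mu\,p(t|D)}{|d|+\mu}$ with $p(t|D) = cf/\text{total
  terms}$ and pseudo-count $\mu$ (default 2000). Query terms unseen in the
  whole collection are skipped, since $p(t|D)=0$ would force $-\infty$.

BM25 and LMD use natural logarithms and DFR uses base 2 (the
information-theoretic convention); rankings within a model are invariant to
the base.

### Querying strategy

Each topic is turned into exactly **seven queries**: {query, question,
narrative} × {title section, abstract section}, plus the concatenated topic
against the whole document. Per-document scores are summed unweighted across
the seven. Two indices are built: a *metadata* index (title + abstract) and a
*full-text* index, in which the abstract section also holds the body text.
Scores from the two indices are never added to each other — they produce
separate runs that are later fused by rank.

Because the outbreak has a well-defined start, documents dated strictly
before 2019-12-01 are filtered out at search time (half-open boundary: the
cutoff date itself is retained). Undated documents are kept by default;
silently dropping them would hide corpus defects, and the flag
`keep_undated = FALSE` makes the stricter choice explicit.

Model parameters can be tuned with `fit_params()`: topics are assigned to
folds deterministically (topic number modulo the fold count, default 5) and
each grid point is scored by mean P@10 over held-out topics, with ties broken
by grid order.

## Fusion and the second stage

**Reciprocal rank fusion.** Given ranked lists $r_1 \dots r_n$, a document's
fused score is $\sum_i 1/(k + r_i(q,d))$ over the lists that contain it, with
$k = 60$ (the value tuned on earlier rounds of the challenge that motivated
this design; overridable per fusion). RRF only consumes ranks, so it is
immune to the wildly different score scales of BM25 and LMD.

**Second-stage scorers.** The package defines a scorer *contract* — a
deterministic total function `(topic, document) -> finite score` — and a
registry. Transformer-based rerankers (the masked-language-model ensembles
used in the original system) are adapters satisfying this contract; the
package ships a deterministic lexical-overlap mock (fraction of a topic
field's terms present in title + abstract, range $[0,1]$) registered in three
instances over the three topic fields. `rerank_topk()` rescores the top
$k$ (study value: 5000; capped at the corpus size on fixtures) of a
first-stage list.

**Logistic score fusion.** `assemble_features()` builds one row per
(topic, document) in the union of the contributing runs, one feature per
model. A document missing from a model's list is imputed with that model's
per-topic minimum minus a fixed unit offset — "worse than anything it
retrieved" — and flagged; the offset's size is immaterial because features
are z-scored before training. Labels binarize the graded judgments
(grades 1 and 2 are relevant). `fit_logistic()` maximizes the L2-penalized
log-likelihood by full-batch Newton ascent with step-halving from zero
initialization — deliberately deterministic (no stochastic optimizer), so
fitted models and downstream run files are exactly reproducible. The
intercept is unpenalized; constant features receive zero weight and the
intercept converges to the logit of the base rate.

### Run recipes

The built-in recipes mirror the seven run designs of the original system:

| Recipe | Composition |
|--------|-------------|
| M1 | BM25 on the metadata index |
| M2 | RRF of {BM25, DFR, LMD} × {metadata, full-text} (six lists) |
| M3 | RRF of the registered rerankers applied to M2's top k |
| M4 | RRF(M2, M3) |
| M5 | slot for a registered pairwise (LambdaMART-style) plug-in |
| M6 | logistic fusion over the individual model scores behind M2 and M3 |
| M7 | RRF(M2, M3, M6) |

M5 is a contract only: pairwise boosting internals are out of scope here, and
the slot raises a configuration error until a plug-in is registered.
Recipes are resolved through an explicit dependency graph with cycle
detection, and misconfiguration (an unregistered scorer, a trained stage
without qrels) fails before any computation starts. The original system
trained M6 on the previous round's judgments; with a single synthetic
collection the supplied qrels play that role, which makes the reported M6/M7
metrics in-sample — adequate for exercising the machinery, not for claiming
generalization.

## Evaluation

`evaluate_run()` computes P@K, NDCG@K, MAP and Bpref per topic and
macro-averaged over topics with at least one judgment. Conventions follow
trec_eval: NDCG uses raw graded gains with the $1/\log_2(i+1)$ discount and
an ideal pool built from all judged grades; unjudged documents count as
nonrelevant for P@K/AP; Bpref condenses the ranking to judged documents only,
and when a topic has no judged nonrelevant document each relevant retrieved
earns full credit. `recency_profile()` bins the publication dates of
judged-relevant documents by week or month, the view that motivates the date
filter in a fast-moving corpus; the package produces the profile but does not
fit a decay model to it.

## The synthetic collection

`generate_collection()` makes the whole pipeline testable offline. Documents
are bags of synthetic terms drawn from a mixture of a Zipf background and
per-theme signature distributions; each theme yields a three-field topic
phrased from its signature terms. Relevance is defined by the generator's own
rule — a same-theme document is graded by its measured signature overlap in
title + abstract (grade 2 at ≥ 75 % of the signature, grade 1 at ≥ 25 %),
plus a fixed number of cross-theme grade-0 judgments — so ground truth is
independent of the systems under test. Dates are drawn with an exponential
lag back from the snapshot date (mimicking a corpus that grows explosively
toward the present), a fraction of documents predate the cutoff, carry no
date, or lack full text — the heterogeneity that makes length normalization
and date filtering matter.

Default sizes are a desk-scale analogue of the study setting: 10 themes ×
20 documents, vocabulary 500, half the documents with full text, 5 % undated,
≈ 28 judgments per topic. These defaults (and the smaller variants used in
unit tests) were chosen once as realistic for the statistics involved; they
are stated here as the package's own study conditions. What passing tests on
this generator shows is that the *machinery* is correct — exact agreement
with brute-force scoring, metric conformance, reproducibility. It does not
show that the shipped mock rerankers approach the behaviour of fine-tuned
language models on real text, nor reproduce the absolute metric values of
the original challenge, which required the full 200 000-document collection
and its official judgments.

`adversarial_pair()` constructs, per topic, two runs with disjoint top-3 sets
that each contain relevant documents, with each run's remaining relevant
documents hidden just below its top — the controlled analogue of the
observation that complementary rankers retrieve disjoint but relevant
documents, where rank fusion provably lifts precision.

## Numerical choices and degenerate inputs

* Ties are broken by ascending `doc_id` everywhere a list is sorted —
  reproducibility over arbitrariness.
* Documents whose total score is exactly zero are never returned; under LMD
  every document containing-or-not the query terms has a nonzero smoothed
  score, so only the `top_k` cap limits the list.
* A zero-length document under LMD collapses to the collection model
  $\ln p(t|D)$ for any $\mu$.
* Run files print scores at six decimal places — enough for stable
  round-trips without bloating files; rank order, not score text, carries
  the information downstream.
* Newton ascent uses step-halving and a gradient max-norm tolerance
  (default 1e-10); the convergence flag is stored on the model.
* Lenient date parsing: `YYYY` → January 1, `YYYY-MM` → first of month,
  anything else → missing.

## Known limitations

* The Porter stemmer is the classic algorithm; no language-specific or
  biomedical variant is provided.
* The shipped second-stage scorers are lexical mocks; semantic matching
  requires registering real scorer adapters.
* The index is rebuilt per corpus snapshot; there are no incremental
  updates.
* No statistical significance testing between runs is provided.
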