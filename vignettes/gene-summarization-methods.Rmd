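---
title: "Methods: learning-to-rank extractive gene summarization"
author: "geneSummarizeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning-to-rank extractive gene summarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most Entrez Gene records lack a curated summary paragraph, while the
literature about any given gene keeps growing. `geneSummarizeR` builds a
five-sentence extractive summary for a query gene by ranking the
sentences of the gene's abstracts and selecting a non-redundant subset.
Ranking is learned: three per-sentence features are combined by a linear
scoring function whose weights are fitted on genes that *do* have a
curated description, using a listwise learning-to-rank loss.

# The model

## Sentence features

Every piece of text passes through one shared preprocessing path:
sentence splitting, tokenization on non-alphanumeric characters,
lowercasing, stopword removal and Porter stemming. Three features are
then computed for each candidate sentence $S_k$ of a query gene:

1. **GO relevance.** The gene's GO annotation term names (from a
   gene2go-style table) are preprocessed into a *GO word set*. The score
   is the fraction of the sentence's token occurrences found in that
   set: each matching occurrence adds 1, and the count is divided by the
   sentence length after preprocessing. Duplicated matches count per
   occurrence — the algorithm iterates over tokens, not types. A gene
   without annotations scores 0 everywhere.

2. **Topic relevance.** An LDA topic model is fitted by collapsed Gibbs
   sampling on the reference gene descriptions of the training split
   (descriptions, not abstracts, are the corpus "about genes" in
   general). For each query gene the most related topic is chosen —
   the topic with the highest summed posterior probability across the
   gene's documents — and its `topM` highest-probability words become
   the topic word set. The sentence score is then the same
   occurrence-fraction computation as for GO relevance.

3. **TextRank.** One weighted graph per gene: nodes are the gene's
   candidate sentences and edge weights are tf-idf cosine similarities
   (zero-similarity pairs carry no edge). Scores follow the damped
   fixed-point iteration
   $$S(V_i) \leftarrow (1-d) + d \sum_{j \in In(V_i)}
     \frac{w_{ji}}{\sum_k w_{jk}}\, S(V_j),$$
   iterated until the largest per-node change falls below the
   tolerance. Because the iteration is a contraction with factor $d$,
   the fixed point is unique and the starting value (any value in
   $[0,1]$) is irrelevant; isolated nodes receive exactly $1-d$.

The idf table treats one abstract as one document:
$idf(w) = 1 + \ln(N/n_w)$ with the natural logarithm (any fixed base
rescales cosine numerator and denominator jointly, so cosines are
base-invariant). Words unseen at scoring time get the smooth extension
$1 + \ln N$.

## Listwise training (ListNet)

Each training gene is a query $q_i$ with feature vectors
$x_{i,1..n_i}$ and relevance labels $y_{i,1..n_i}$; the label of a
sentence is its tf-idf cosine similarity to the gene's reference
description. The scorer is linear, $z_{i,j} = w \cdot x_{i,j}$, and the
loss per list is the top-one cross-entropy
$$L(y_i, z_i) = -\sum_j P_{y_i}(j) \log P_{z_i}(j), \qquad
  P_s(j) = \frac{e^{s_j}}{\sum_k e^{s_k}},$$
minimised over the *sum* of all training lists by full-batch gradient
descent with the analytic gradient
$\sum_j (P_z(j) - P_y(j))\, x_j$. The objective is convex in $w$
(log-sum-exp minus a linear term), so with the default step size the
loss trace is non-increasing; the implementation verifies finiteness at
every step and the test suite asserts monotonicity. A reported
three-component weight vector is the entire learned model, which is why
the scorer is linear rather than a deeper network.

Labelling alternatives: the default is the cosine label above
(`labelMode = "eq3"` in `pipelineConfig()`); a coarse variant bins
ROUGE-1 recall of each sentence against the description into five
equal-width grades 0–4 (`labelMode = "rouge_grade"`, rescaled to
$[0,1]$). The cosine mode is the default because it is the only
labelling with an explicit formula; the grade mode is provided for
completeness.

## Redundancy removal

Given model scores, the summary is assembled greedily: repeatedly move
the highest-scoring candidate $s_i$ into the summary, then penalise
every remaining candidate by
$$Score(s_j) \leftarrow Score(s_j) - \omega \cdot sim(s_i, s_j),$$
with $\omega = 1$ by default and $sim$ the tf-idf cosine. Penalties
accumulate across iterations; selection stops at the target length
(five sentences) or when candidates run out. Ties break toward the
earlier document position, and the output preserves selection order and
records both the penalised selection score and the original model
score, since either may be of interest downstream.

## Evaluation

ROUGE-1, ROUGE-2 and ROUGE-SU4 are implemented in-package: clipped
multiset n-gram overlap, and for SU4 the union multiset of unigrams and
skip-bigrams with at most four intervening words ($j - i \le 5$; the
boundary pair with five intervening words is excluded). Recall divides
by the reference's unit count, precision by the candidate's, F is the
harmonic mean. By default both summary and reference are preprocessed
with the system's own tokenizer (stemmed, stopword-stripped) so the
metric operates in the same token space the ranker does; a raw-token
mode is available (`rawTokens = TRUE`). One reference per gene is
assumed.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `d` | 0.85 | TextRank damping; canonical PageRank value |
| `tolerance` | 1e-6 | TextRank convergence threshold (per-node change) |
| `K` | 10 | LDA topics; `alpha = 50/K`, `beta = 0.01` |
| `topM` | 24 | topic words kept for the topic feature |
| `ldaIterations` | 1000 | Gibbs sweeps |
| `learningRate` | 0.01 | gradient-descent step size |
| `nIterations` | 1000 | gradient steps |
| `omega` | 1.0 | redundancy penalty weight (empirical value) |
| `targetLength` | 5 | summary length in sentences |
| `trainFrac` | 2/3 | leading fraction of sorted gene ids used to train |

`K` deserves a caveat: no principled value exists for a given corpus,
and downstream ROUGE can depend on it. For the synthetic experiments
shipped with the package, `K` is set to the number of planted topics
(4), which is the honest choice when the generating process is known;
on real corpora `K` should be explored.

# Design choices where the design was open

* **TextRank denominator.** The vote of neighbour $j$ is normalised by
  its *weighted degree* $\sum_k w_{jk}$, the standard weighted-graph
  extension; normalising by the neighbour *count* is available via
  `denominator = "count"`. The weight-sum reading makes scores
  invariant to rescaling all edge weights, which is the behaviour one
  wants from a similarity-weighted graph.
* **Topic set scope.** Topic words are selected per gene (the most
  related topic *of that gene*); a single corpus-wide topic set is
  available via `globalTopicSet = TRUE`. Per-gene selection uses the
  gene's candidate abstracts, because test genes have no description to
  infer from — training and test genes must be treated identically.
* **Document-topic inference for selection** uses a
  one-topic-per-document approximation
  ($\log P(k \mid doc) \propto \log\alpha + \sum_{w} \log\phi_{k,w}$)
  rather than a second Gibbs fold-in: it is deterministic, cheap, and
  only the argmax over topics is consumed.
* **Feature scaling.** GO and topic scores are already fractions in
  $[0,1]$; TextRank scores are min–max scaled to $[0,1]$ within each
  query so that one fixed step size behaves uniformly across genes. A
  gene whose sentences all tie gets zeros (the feature is then
  uninformative for that gene by construction).
* **Stemming and splitting.** The Porter algorithm is implemented from
  its published rule tables (words under three letters and tokens with
  non-alphabetic characters pass through). Sentence boundaries are a
  deterministic rule — terminator, whitespace, uppercase — with a small
  abbreviation list (`et al.`, `e.g.`, `Fig.`, single-letter initials
  such as `E. coli`). These are reasonable defaults for abstracts, not
  reconstructions of any particular toolchain.
* **Empty-sentence conventions.** A sentence with no tokens after
  preprocessing scores 0 on both word-set features (with a warning);
  an empty candidate set yields an empty summary with a warning; an
  empty reference makes the label undefined and is an error.

# The synthetic corpus generator

`generateCorpus()` emulates the structure of a per-gene literature
corpus without any external data: each gene receives GO annotation
rows (synthetic two-word term names), a dominant topic from a small set
of planted disjoint topic word blocks, and abstracts in which a few
planted *signal* sentences draw most of their tokens
(`signalFraction = 0.7`) from the gene's GO and topic words while noise
sentences draw from a shared background vocabulary. The reference
description is the concatenation of the signal sentences with words
replaced by synonyms at rate `noiseRate = 0.1`, so even perfect
selection cannot reach ROUGE of 1. Stopwords are injected so the
preprocessing stage is genuinely exercised, and all output is a pure
function of the configuration and seed.

What this does *not* emulate: real Medline language statistics,
polysemy, sentence-length and section structure, genes whose GO
annotations are uninformative, or descriptions written independently of
any abstract. Passing the shipped experiments therefore demonstrates
that the pipeline's machinery is correct and that its qualitative
behaviour (learning helps; each feature contributes) holds when the
corpus actually contains the planted structure — not that any
particular ROUGE level would be attained on real literature.

`generateLtrInstances()` is the companion generator for the ranking
module alone: features uniform on $[0,1]^3$, labels the softmax of the
true scores $w^\* \cdot x$ per list plus Gaussian noise clipped to
$[0,1]$. Its standard setting — true weights $(0.1, 0.2, 0.7)$, 500
lists of 10, noise 0.05 — drives the weight-recovery experiment, with
recovery measured as mean Kendall $\tau$ between the trained and true
score rankings on held-out lists.

# Numerical choices

* Softmax and its logarithm are computed with a max shift; top-one
  probabilities sum to 1 within 1e-12.
* TextRank convergence is declared when the max per-node change drops
  below the tolerance; exceeding `maxIterations` is an error naming the
  residual rather than a silent partial result.
* The Gibbs sampler uses R's RNG (seeded per call and restored
  afterwards), so equal seeds give bit-identical topic models and
  library calls never perturb user-level random streams.
* Model and topic-model files are plain versioned text; topic rows are
  renormalised on read to absorb decimal round-trip error.

# Problem sizes in the shipped experiments

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute: the study corpus is 30
genes × 4 abstracts × 6 sentences (20 training genes, 10 test genes),
LDA uses 500 sweeps with `K = 4`, training 500 iterations, and the
random baseline averages 10 draws. The weight-recovery experiment uses
the standard 500-list fixture with the module defaults (step 0.01,
1000 iterations). Oracle checks (TextRank linear solve,
finite-difference gradients, brute-force ROUGE enumeration) run on 50 to
100 randomized small cases each.

# Known limitations

* Word-level GO matching only: no traversal of the GO graph's *is a* /
  *part of* relations, and GO accession strings never match sentence
  text.
* Single reference per gene; no multi-reference ROUGE aggregation, no
  bootstrap confidence intervals, no ROUGE-L.
* The linear scorer cannot express feature interactions; that is the
  price of an interpretable three-component weight vector.
* The sentence splitter and stemmer target English abstracts; full-text
  PDFs and other languages are out of scope.
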