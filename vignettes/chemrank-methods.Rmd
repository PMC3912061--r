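---
title: "Ranking drug indications from chemical-chemical interactions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug indications from chemical-chemical interactions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemrank)
```

## The model

chemrank implements a guilt-by-association, multi-label *ordered*
prediction model for drug indications. The operating assumption is label
homophily: compounds that interact — share reactions, structures,
activities or literature associations, as catalogued by databases such
as STITCH — tend to treat the same diseases.

Let the training set contain $n$ drugs $d_1,\dots,d_n$ over a fixed
catalogue of $M$ indication categories $C_1,\dots,C_M$. Each training
drug carries a binary indicator vector $y_i \in \{0,1\}^M$, with
$y_{ik} = 1$ iff drug $i$ treats category $k$; multi-label drugs are
allowed and common. Let $Q(c_1, c_2) \ge 0$ be the interaction
confidence score of a compound pair (STITCH's `combined_score`, on a
0–1000 scale); two compounds are interactive iff $Q > 0$, and absent
pairs score exactly 0. For a query drug $q$ the evidence for category
$k$ is

$$ S_k(q) \;=\; \sum_{i:\, d_i \neq q} Q(q, d_i)\, y_{ik}, $$

i.e. every interactive training partner votes for its own indications
with weight equal to the interaction confidence. The prediction is the
full ordering of all $M$ categories by decreasing $S_k$: the category at
position $j$ is the *j-th order prediction*. A zero score means the
query has no interactive partner treating that category.

Two consequences shape the implementation:

* **Scale equivariance.** Multiplying all confidence scores by
  $\lambda > 0$ rescales all $S_k$ but changes no ranking, so scores are
  used raw, with no normalisation.
* **Exact leave-one-out.** The only term a drug could contribute to its
  own score is the self-term $Q(q, q)$, which is never stored (self
  interactions are rejected at load). Scoring a training drug against
  the full set is therefore identical to retraining without it, which
  makes the jackknife exact and cheap; the test suite asserts equality
  with an explicit leave-one-out double loop.

### Ties and full-length rankings

The evaluation statistics require every category to occupy exactly one
rank, so rankings are full-length by default: categories with zero (or
equal) scores are kept and ordered by ascending catalogue position, a
deterministic, auditable tie policy. Runs of exactly equal scores
(floating-point equality on the sorted score vector) are recorded as
*tie groups* in each prediction, so any alternative tie-breaking policy
can be audited after the fact. A `truncate_zero` mode that drops the
zero-evidence tail is available for presentation, but all evaluation
code assumes full-length rankings.

### The descriptor comparator

The comparison method replaces the interaction confidence with the
cosine similarity of molecular-descriptor vectors,

$$ S_k(q) = \sum_{i:\, d_i \neq q} \cos(x_q, x_{d_i})\, y_{ik}, \qquad
   \cos(u, v) = \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert}, $$

and is otherwise identical. Descriptor matrices (e.g. quantum-chemistry
descriptor suites) often contain columns with missing values for some
molecules; the loader drops every incomplete column (a 454-column suite
typically reduces to ~355 usable descriptors). Three numerical
conventions, each chosen where the formula itself is silent:

* a zero-norm vector has cosine 0 to everything (neutral evidence, with
  a warning);
* negative cosines are summed as-is — the formula has no clipping and
  negative structural evidence legitimately lowers a category;
* descriptors are used raw by default; an optional `standardise` flag
  z-scores columns first, off by default because the method is defined
  on the literal vectors.

## Evaluation statistics

All metrics are computed in full precision; reports print two-decimal
percentages.

* **j-th order accuracy** $Q_j$: the fraction of drugs whose j-th
  ranked category is one of their true categories. $Q_1$ is the
  headline number; a good ranker has high $Q_j$ at low $j$ and a
  generally descending profile.
* **Per-category order accuracy**: for category $k$ with $N_k$ member
  drugs, the fraction whose i-th rank is exactly $k$. When $N_k = 0$
  the entry is undefined and reported as `NA` — deliberately distinct
  from a genuine 0% over a non-empty denominator. With full-length
  rankings each column of the matrix sums to exactly 1, a built-in
  consistency check.
* **Coverage ratio** $r(m)$: the fraction of all true drug–indication
  pairs recovered within each drug's first $m$ predictions. The cutoff
  $m$ defaults to the ceiling of the dataset's average indications per
  drug (`choose_m()`); e.g. 77 pairs over 59 drugs average 1.31, so
  $m = 2$, while 34 pairs over 9 drugs average 3.78, so $m = 4$.
  $r(M) = 1$ always, for full-length rankings.
* **Precision / recall** for unordered predicted sets:
  $\mathrm{P} = \frac1N \sum_i c_i/p_i$,
  $\mathrm{R} = \frac1N \sum_i c_i/n_i$. Taking each drug's first-order
  prediction as a singleton set makes precision *identically* equal to
  $Q_1$ — an identity the test suite asserts exactly.
* **Uniform-guess baseline**: guessing one of $M$ categories uniformly
  succeeds with expected rate (average labels per drug)$/M$.
  `uniform_guess_rate()` also offers a `rounded` variant that rounds
  the average to two decimals before dividing, reproducing the rounding
  convention of published benchmark tables (1.31/8 = 16.38% rather than
  the full-precision 16.31%); reports can print both.

Validation- and independent-set protocols score queries against the full
training set (no leave-one-out). Drugs absent from the network evaluate
as all-tied catalogue-order rankings rather than being dropped; a
`--drop-isolated` CLI flag reproduces the alternative curation choice of
discarding them.

## Null controls

* **Random label transfer**: each drug receives the true label set of
  one uniformly drawn other drug; evaluated by precision/recall since
  the transferred set is unordered.
* **Uniform category guess**: one uniform category per drug; its hit
  rate converges to the uniform-guess baseline above.
* **Score permutation**: the pair set is kept fixed and the multiset of
  confidence scores is reassigned by a uniform random permutation
  ("exchanging the confidence scores"), operationalised as a full
  permutation over all edges — the strongest parameter-free reading —
  with a `fraction` option for partial permutation as sensitivity
  analysis. Edge count and score multiset are conserved exactly.

All randomness is driven by explicit integer seeds; seeded calls leave
the caller's RNG stream untouched.

## The synthetic-data generator

`generate_synthetic()` produces the three inputs every module consumes —
a labelled drug set, an interaction network, a descriptor matrix — with
the statistical structure the method assumes, so the whole pipeline is
testable without any database download.

* **Labels**: a primary category drawn from `category_weights`, plus a
  second distinct category with probability `multi_label_prob`
  (default 18/68, the multi-label drug fraction of the cancer benchmark
  the method was developed on). An *exact-count mode* instead deals
  shuffled category slots so the per-category column sums hit requested
  marginals exactly, with `n_multi` drugs receiving at least two
  labels; this reproduces benchmark-shaped datasets such as the
  59-drug/77-pair training marginals or the 9-drug/34-pair validation
  marginals (where drugs average 3.78 indications).
* **Network**: each pair is connected independently with probability
  `p_within` if the drugs share a label and `p_between` otherwise
  (topological homophily), with integer scores drawn uniformly from
  `score_range` (default 150–999, the usable part of STITCH's 0–1000
  scale).
* **Score-borne homophily**: `score_range_between` lets between-category
  edges draw from a different (lower) score range than within-category
  edges. This matters for the permutation control: if the homophily
  signal lives only in the topology, permuting scores leaves rankings
  essentially intact, because per-category score sums still track
  neighbour counts (we verified $Q_1$ is unchanged at 0.95 in that
  regime). The score-permutation control specifically probes whether
  the score *magnitudes* carry information, so its fixture uses a
  label-blind topology (`p_within = p_between`) with high within- and
  low between-category scores; permutation then collapses $Q_1$ by
  ~80%, qualitatively mirroring the collapse seen on the real cancer
  benchmark.
* **Descriptors**: each category gets a random unit direction in
  `descriptor_dim`-space; a drug's vector is the mean of its
  categories' directions scaled by `descriptor_effect` plus standard
  normal noise, so within-category cosine similarity is elevated when
  the effect is positive.

Same seed, same bundle — fixtures written twice are byte-identical.

What the generator does *not* emulate: real chemical structure, the
long-tailed degree distribution and channel composition of literature-
mined interaction databases, correlated descriptor blocks, or curation
artefacts. Passing the synthetic checks therefore demonstrates
correctness of the machinery and recoverability of planted homophily
signal, not the accuracy level attainable on any real benchmark;
reproducing published benchmark accuracies requires the original
interaction database version and identifier mapping, supported through
the readers and CLI as an external workflow.

## Verification at a glance

The test suite checks every scorer and metric against independent
brute-force oracles (exhaustive double loops) on 100 random instances of
up to 12 drugs and 8 categories — exact equality for count-based
metrics, 1e-12 relative for floating sums. Parameter recovery uses 20
datasets of 200 drugs at an edge-probability ratio of 90
(`p_within = 0.9`, `p_between = 0.01`), where mean jackknife $Q_1$
exceeds 0.8 (in practice ≈ 1), and 20 no-signal datasets
(`p_within = p_between`) where $Q_1$ stays within 3 Monte-Carlo standard
errors of the uniform-guess baseline. The permutation control runs 50
score permutations on a 120-drug score-homophilous fixture and requires
a >50% relative drop in $Q_1$. These problem sizes keep the whole suite
under half a minute on one CPU.

## Known limitations

* One-hop evidence only: no network propagation, no weighting of the
  four sub-channel scores.
* The method cannot rank a query with no interactive partner (all-tied
  output); how to handle such drugs is a curation decision surfaced via
  `--drop-isolated`, not solved by the model.
* Tie handling inside equal-score runs is a convention (catalogue
  order); recorded tie groups make the convention auditable but results
  at tied ranks remain convention-dependent.
* Identifier reconciliation across databases (KEGG / DrugBank / STITCH
  CIDs) is delegated to a user-supplied mapping table; no prefix logic
  is hard-coded.
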