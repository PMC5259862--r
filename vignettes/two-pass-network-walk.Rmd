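---
title: "Two-pass restart walks on a drug-disease heterogeneous network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pass restart walks on a drug-disease heterogeneous network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugwalker)
```

## The problem and the model

Drug repositioning asks which approved drugs might treat diseases they
were never indicated for. `drugwalker` ranks all unobserved drug-disease
pairs by diffusion on a heterogeneous network with two node types: drugs,
connected by a fused chemical/association-derived similarity; diseases,
connected by a fused phenotypic/association-derived similarity; and the
known associations bridging the two layers.

The walk model is random walk with restart. With row-stochastic
transition matrix $T$ (drugs first, then diseases), restart probability
$\alpha$ and seed distribution $P_0$,

$$P(t+1) = (1-\alpha)\,T'P(t) + \alpha P_0,$$

where $T'$ is the **transpose** of $T$. The transpose is the standard
column-action convention — entry $(j,i)$ of $T'$ moves mass from node $i$
along the transition $i \to j$ — and we state it explicitly because the
iteration is sometimes written with a row-action matrix instead. For
$\alpha > 0$ the affine map is a contraction with factor $1-\alpha$ in
the L1 norm, so the fixed point $P^* = \alpha\,(I - (1-\alpha)T')^{-1}P_0$
is unique and independent of where the iteration starts. We start at
$P(0) = P_0$; this choice only affects the step count, never the result.
The test suite verifies the iterative solution against this closed-form
solve on hundreds of random networks.

Each candidate pair $(c_i, d_j)$ is scored twice: a *drug-centric* walk
is seeded at $c_i$ and its known diseases and read out at $d_j$, and a
*disease-centric* walk is seeded at $d_j$ and its known drugs and read
out at $c_i$. The two passes are asymmetric label-propagation processes
and carry complementary information; the confidence score is their plain
mean. `compare_passes()` quantifies what the averaging buys over either
single pass on the same folds.

## Similarity construction

Two measures per node type, fused by probability disjunction
$w = 1-(1-w_1)(1-w_2)$ (treating the two sources as independent evidence
of relatedness; the result dominates both inputs and stays in $[0,1]$):

* **Fingerprint Jaccard** (drugs): shared substructure bits over total
  bits. Any fingerprint width is accepted; nothing is hard-coded to a
  particular fingerprint dictionary.
* **Concept-vector cosine** (diseases): cosine between nonnegative
  phenotype term-weight vectors, hence in $[0,1]$.
* **Bipartite projection** (both sides): two-step resource allocation
  over the association network,
  $w^{(c2)}_{ij} = \frac{1}{k(c_i)}\sum_l \frac{a_{il}a_{jl}}{k(d_l)}$.
  Rows of connected nodes sum to exactly 1 (each node redistributes one
  unit of resource), and the measure is deliberately asymmetric — a
  promiscuous drug receives more than it returns. We never symmetrize
  the fused matrices: row-wise normalization in the transition matrix
  makes the walk well-defined either way.

Degenerate-input conventions, chosen so that "no evidence" never becomes
`NaN`: an all-zero fingerprint or concept vector has similarity 0 to
everything including itself; a node with no associations has an all-zero
projection row.

## Transition matrix

`build_transition()` assembles $T$ blockwise. A drug with associations
splits its mass $(1-\lambda)$ over similar drugs (row-normalized
similarity) and $\lambda$ over its associated diseases (uniformly); a
drug without associations keeps all mass in the drug layer; diseases are
dual. $\lambda = 0$ therefore zeroes both cross blocks and confines a
walker to the layer it started in.

Numerical choices:

* **Similarity diagonals are zeroed before normalization** (default,
  switchable via `zero_diagonal`). A self-loop would siphon a large
  share of each row's mass into standing still, diluting the diffusion
  signal; the walk semantics are jumps between distinct nodes.
* **Associations but no similarity mass**: the $(1-\lambda)$ intra-layer
  share has nowhere to go, so the full unit routes across the bipartite
  edges (row rescaled to 1), with a warning. This keeps the matrix
  stochastic instead of silently leaking.
* **Neither associations nor similarity mass**: an all-zero row. The
  walk then loses mass through that absorbing leak, which the restart
  term $\alpha P_0$ continually replenishes; $\sum P^* \le 1$ in that
  case. `assert_stochastic()` reports such nodes.
* **Storage**: dense base matrices up to 3000 nodes, sparse
  (`Matrix::dgCMatrix`) beyond; both paths run through the same
  arithmetic and the tests require identical results.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lambda_jump` | probability of crossing layers along an association | 0.8 | 0 isolates the layers; 1 sends connected nodes fully across |
| `alpha_restart` | teleport-to-seed probability per step | 0.3 | controls diffusion range; also the contraction rate $1-\alpha$ |
| `eta_tradeoff` | seed mass on the query node vs. its cross-type associates | 0.4 | at 1, all seed mass on the query node |
| `epsilon` | L1 convergence tolerance | 1e-10 | with $\alpha=0.3$, convergence needs at most a few dozen iterations |
| `max_iter` | iteration cap | 10000 | non-convergence is an error, never a silent truncation |

All are validated at construction (`walk_config()`). A query drug with
no known diseases has no cross-type seed set; it gets full unit mass on
itself ($\eta$ effectively 1), so new drugs remain scorable; dually for
diseases.

## Ranking, ties, and evaluation

Candidates are all pairs absent from the (training) association matrix;
known training edges have well-defined scores but are never ranked.
Ordering is by mean probability descending with lexicographic
`(drug_id, disease_id)` tie-break, so ranks are a deterministic
permutation across platforms.

Cross-validation splits the *associations* (not the drugs or diseases)
into `n_folds` test sets differing in size by at most one. Per fold, the
association-derived similarity components and the transition matrix are
rebuilt from training edges only — the test suite checks leak-freedom by
verifying that a fold's scores are a pure function of its training
edges. Reported metrics:

* **AUC** by the rank (Mann-Whitney) formulation with ties counted one
  half, verified exactly against brute-force concordance counting. The
  headline curve pools the candidates of all folds — pooling matches
  "ranking all candidate associations" — and per-fold AUCs plus their
  mean are reported alongside.
* **Top-rank hits**: a held-out association counts as recovered at
  threshold $t$ if it ranks $\le t$ (inclusive boundary — "at or above
  the threshold" is the reading we document) among its disease's
  candidate drugs. Per-disease ranking matches how case-study queries
  are posed ("top predicted drugs for disease X"); a per-drug mode is
  available via `hits_by = "drug"`. Negatives are all unknown pairs in
  the fold's candidate set; nothing is subsampled.

## What the synthetic generator does and does not show

`simulate_fixture()` plants matched drug/disease blocks: associations are
dense within matching blocks (`within_density`, default study condition
0.5) and sparse elsewhere (0.02); fingerprints are per-block prototypes
with independent bit flips; concept vectors are per-block prototypes
with clipped Gaussian noise (`concept_signal = FALSE` decouples the
concept vectors from the blocks, leaving the signal only in the
fingerprints — the complementary-information setting used to probe when
two passes beat one). Components draw from sub-streams at fixed seed
offsets, so the generator is a pure function of its arguments and adding
a component never perturbs earlier draws.

The standard problem size used throughout the checks is 40 drugs x 30
diseases x 3 blocks with 128-bit fingerprints, and the walk checks run on
networks up to 200 nodes — sizes at which the closed-form linear solve
remains a practical oracle. On these fixtures the pipeline attains pooled
cross-validated AUCs around 0.83-0.86; the acceptance checks require
> 0.75 over ten seeds.

A planted-block model is a deliberately idealized world: blocks are
clean, noise is independent, fingerprint bits are exchangeable, and
similarity signal is strong. Passing these checks demonstrates that the
implementation recovers signal its model assumes — it does not certify
performance on real pharmacopeias, where associations are incomplete and
biased toward well-studied drugs, similarity structure is far from block
constant, and hub diseases dominate the degree distribution. Evaluating
against curated drug-disease corpora requires those external datasets
themselves and is out of scope here.

## Known limitations

* Associations are strictly binary; quantitative (dose- or
  evidence-weighted) edges are not modeled.
* The two intra-type measures per side are fixed (Jaccard + projection,
  cosine + projection); alternative fusion rules or similarity
  sparsification cutoffs are not provided.
* Single-pass rankings exist for comparison (`compare_passes()`) but are
  not a supported prediction surface on their own.
* Fingerprint and concept-vector *generation* (from SMILES, from
  phenotype text mining) is upstream of this package; it consumes their
  tabular output.
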