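---
title: "Pathway-type prediction from heterogeneous networks: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-type prediction from heterogeneous networks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnetpath)
```

## The model

`hnetpath` predicts which of the metabolic pathway types a chemical or an
enzyme belongs to — a multilabel problem, since pathway membership
overlaps — from nothing but weighted association networks. The premise is
that interaction neighbourhoods encode pathway membership: two molecules
that interact, directly or through short weighted paths, tend to work in
the same pathway types. The pipeline has three stages.

**Diffusion.** The chemical-chemical, chemical-protein and protein-protein
subnetworks are combined into one undirected weighted network over both
node kinds. For node $i$ the random walk with restart iterates
$p \leftarrow (1-r)\,P\,p + r\,e_i$ with $P$ the column-stochastic
transition matrix ($P_{kj} = w_{kj} / \mathrm{deg}_w(j)$), producing the
diffusion state $V_i$, a stationary proximity distribution over all $n$
nodes. The walk mixes across node kinds, which is the point: a chemical's
diffusion state contains enzyme proximities and vice versa.

**Embedding.** The $n \times n$ diffusion matrix is reduced to $d$
dimensions by choosing feature vectors $X_i$ and context vectors $W_k$
that minimize the average KL divergence

$$\frac{1}{n}\sum_{i=1}^{n} D_{KL}\!\left(V_i \,\Big\|\,
  \widetilde V_i\right), \qquad
  \widetilde V_{ik} = \frac{\exp(X_i^\top W_k)}
  {\sum_{k'} \exp(X_i^\top W_{k'})}.$$

Because the softmax model matches $V$ exactly when
$X_i^\top W_k = \log V_{ik}$ up to a per-column constant, the default
solver is a truncated rank-$d$ SVD of $\log V$: deterministic, fast, and at
$d = n$ an exact factorization. The faithful objective is also available as
`method = "kl_gradient"`: full-batch gradient descent from a small seeded
uniform init, recording the objective trace. $X$ is the downstream feature
matrix.

**Classification.** RAKEL draws $M$ random $k$-subsets of the $m$ labels.
Each subset induces a label-powerset (LP) problem — every observed label
combination restricted to the subset becomes one class — solved by a
multiclass base learner. At prediction time each member's class is expanded
back into binary votes on its labels; a label is assigned when its average
vote over covering members strictly exceeds the threshold (0.5). Binary
relevance (one independent classifier per label) is exactly RAKEL with
$k = 1$ and a full singleton cover, and the package keeps the two routes
bit-identical, including for seeded random forests.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `restart_prob` | 0.5 | restart mass per step; the common Mashup-style convention. Larger values localize the diffusion states. |
| `tol`, `max_iter` | 1e-8, 1000 | L1 stopping rule of the power iteration; the fixed point is unique, so `tol` only sets accuracy. |
| `d` | 250 | embedding dimension for real-scale data (grids usually span 50–300); synthetic benchmarks use 32, ample for 5 labels on 180 nodes. |
| `k`, `M` | 11, 5 | labelset size and ensemble size; `k = m` makes every member the same full LP problem, `k = 1` with full cover is binary relevance. |
| kernel, `C`, `E`/`gamma` | poly, 2, 1 | the SMO-style SVM of `e1071` with `(u·v + 1)^E`; one-vs-one multiclass voting. |
| `threshold` | 0.5 | vote cut-off; assignment requires *strictly greater*, so a tie votes against the label. |

## The synthetic generator

Real association data cannot be redistributed here, so the generator plants
the property the method exploits. Each node draws 1–2 labels out of
$m = 5$ (uniform count, labels without replacement — mean multiplicity 1.5,
close to the 1.25–1.5 of curated pathway memberships); node pairs sharing a
label connect with probability `p_intra`, others with `p_inter`; shared
edges draw weights in [0.500, 0.999], others [0.001, 0.499], quantized to
3 decimals so the 1–999 integer score dialect round-trips exactly. Nodes
left isolated are rewired to one label-sharing partner, so the pruning step
provably removes nothing. Presets: easy (0.25 / 0.02), medium
(0.15 / 0.04), hard (0.08 / 0.04) over 120 chemicals + 60 enzymes.

What the generator does *not* emulate: the heavy-tailed degree
distributions of STITCH/STRING, realistic label co-occurrence structure,
evidence-channel correlations, and the order-of-magnitude larger scale of
the real data. Passing tests on these fixtures therefore demonstrate the
*mechanics* of the method — diffusion, factorization, ensemble voting,
evaluation — and the recoverability of a planted signal, not performance on
real catalogues.

## Numerical choices

* **Pseudo-count in the log.** `log V` needs a guard when diffusion states
  contain zeros (disconnected components). The pseudo-count is `1/n`, but
  only when nonpositive entries are present; for strictly positive $V$ (any
  connected network) no pseudo-count is added, keeping the full-rank
  factorization exact. A constant pseudo-count would shift every
  reconstructed column towards uniform and break exactness.
* **Gradient route.** Step size 0.1, halved whenever a step would increase
  the objective (retrying the same step), so the recorded trace is
  monotonically non-increasing; init entries uniform(−0.01, 0.01) from a
  fixed seed; bit-reproducible.
* **Duplicate edges** (same unordered pair twice, or both orientations)
  keep the maximum refined score: deterministic, order-independent,
  preserves the strongest evidence.
* **Ties and degenerate cases.** A vote average exactly at the threshold
  does not assign the label. LP members that observe a single class warn
  and predict it constantly. Labels uncovered by every labelset warn at fit
  time and are never predicted. Labelset draws that miss a present label
  are redrawn with stepped seeds while coverage is feasible
  (`k · M ≥` number of present labels); otherwise the gap is reported
  rather than hidden.
* **LP class space** is the set of label combinations observed in training
  (standard LP); a single member cannot predict an unseen combination, but
  the ensemble's label-wise votes can.
* **Cross-validation** uses a plain seeded random partition into near-equal
  folds (no stratification by default — a stratified option was considered
  and left out to keep fold assignment transparent), and metrics are pooled
  over the out-of-fold predictions of all $n$ samples rather than averaged
  per fold, because every measure is defined as a mean over samples and
  each sample is tested exactly once.
* **No feature scaling** by default: Mashup-style coordinates already share
  a scale (singular-vector columns weighted by singular values); a
  standardization flag exists on `base_config()`.

## Open design points, as resolved here

* The combined network is embedded as *one* network rather than averaging
  three single-network diffusions; the cross-kind edges are the method's
  premise, and separating them is precisely the ablation
  (`ablation_separate()`, and feature-level separation by embedding the
  chemical and protein subnetworks individually).
* Features are $X$ alone, not $[X; W]$.
* With $k = m$ every member solves the identical LP problem, so a
  deterministic base learner makes all $M$ members identical; the package
  deduplicates those fits (a pure optimization — predictions are
  unchanged). Random-forest members always refit with per-member seeds.
* Node identifiers are opaque strings; kind comes only from the roster
  files. Identifier mapping between catalogues is out of scope.

## Problem sizes used in the shipped checks

The test-suite and reference scripts run at desk scale, chosen as the
smallest sizes at which every property is informative: 180-node benchmarks
with $d = 32$ embeddings for end-to-end recovery and permutation-direction
checks (10 seeds), networks of up to 20 nodes against a dense linear solve
for RWR correctness (50 seeds), a 5-node network for exact full-rank
reconstruction, and $n \le 12$, $m = 3$ instances for exhaustive
enumeration of the labelset-vote procedure with a 1-nearest-neighbour base
learner.

## Known limitations

* Diffusion states are computed by dense per-seed power iteration;
  $O(n^2)$ memory and $O(n^2)$ work per seed are fine into the low
  thousands of nodes but not beyond (the real-scale alternative is a
  sparse solver, out of scope here).
* The KL gradient route is a reference implementation of the objective,
  not a tuned optimizer; the SVD route is the practical default.
* Hard-vote expansion (no probability calibration of members) follows the
  classical RAKEL description; calibrated votes could change behaviour
  near the threshold.
* Unseen label combinations are unpredictable for any single LP member;
  with small training sets and large $k$ this caps exact-match.
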