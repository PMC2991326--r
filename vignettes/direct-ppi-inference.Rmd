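---
title: "Inferring direct protein interactions from AP-MS connectivity matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring direct protein interactions from AP-MS connectivity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppideconv)
```

## The problem

Affinity purification followed by mass spectrometry (AP-MS) pulls down a
tagged bait protein together with everything attached to it — directly
bound partners as well as proteins connected only through chains of other
physical contacts in the same complex. The observable is therefore a
mixture of direct and indirect interactions, and the question this package
addresses is how to separate them when quantitative abundance estimates
(peptide counts) are available for every bait–prey pair.

## The model

The hidden direct-interaction network is an undirected graph $G = (V, E)$.
During a purification, each direct interaction survives independently with
a uniform probability $\hat p$ (0.5 by default, the value at which the
model agrees best with large-scale yeast AP-MS data), and all interactions occur
simultaneously and at equal frequency. Under these assumptions the
expected relative abundance of prey $v$ under bait $u$ is the probability
$P_G(u, v)$ that $u$ and $v$ remain connected after the random edge
deletions — the *two-terminal reliability* of the pair. The $n \times n$
matrix of these probabilities is the **connectivity matrix**; its observed,
noisy counterpart $M$ is the input to inference. Recovering $G$ from $M$ is
posed as an optimization problem: find the graph whose connectivity matrix
matches $M$ at as many vertex pairs as possible, to within an additive
tolerance $\delta$ that accounts for sampling error.

Exact two-terminal reliability is #P-complete, so $P_G$ is estimated by
Monte-Carlo sampling: each realization deletes every edge independently and
labels connected components once, and every co-component pair is counted.
The per-entry estimate is a binomial proportion whose worst-case 95%
half-width is $\delta = z_{0.975} / (2\sqrt{n})$ — `sampling_half_width()`;
0.007 at 20,000 samples, 0.04 at 500. An exact enumerator over all
$2^{|E|}$ edge subsets (`exact_connectivity()`, capped at 22 edges, with a
closed-form shortcut for forests) serves as the small-instance oracle, and
series/parallel composition laws plus the exact clique reliability
`clique_conn()` cover the structured cases.

## The three inference phases

**Phase I — weakly connected vertices.** A pair $(u,v)$ is a cut edge of
$G$ exactly when $M(u,v) = \hat p$ and the partition
$V_u = \{x : M(x,u) \ge M(x,v)\}$, $V_v = V \setminus V_u$ satisfies the
series factorization $M(s,t) = M(s,u)\,\hat p\,M(v,t)$ for every pair
crossing it. Detected cut edges split the matrix into two independent
subproblems (within-side entries are unchanged), and the recursion
continues until no pair qualifies; vertices whose incident edges are all
cut edges (*1-cut vertices*) end up fully resolved. On the exact matrix of
a tree this recovers the entire graph. Degree-2 vertices obey three
necessary row conditions — connectivity bounded by
$2\hat p - \hat p^2$, a two-way tied maximum at the two neighbors, and a
triangle inequality against those neighbors — which yields a high-recall
flagging rule; flagged vertices are marked rather than removed, because
deleting them would change the remaining entries.

**Phase II — dense regions.** Every pair inside a $k$-clique is connected
with probability at least $t_k = $ `clique_conn(k, p_hat)`, so thresholding
$M$ at $t_k$ (minus $\delta$ on sampled input) and enumerating maximal
cliques of the threshold graph finds every true clique of size $\ge k$,
along with false positives that are tolerated: the regions only seed the
genetic algorithm's initial population and guide its crossover cuts. The
default sweep runs $k = 7, 6, 5$, keeping maximal regions.

**Phase III — cut-based genetic algorithm.** What remains after Phase I is
the *hard core*: the densely connected residual. Chains of flagged
degree-2 vertices between core vertices are contracted to meta-edges with
survival probability $1 - \prod_i (1 - \hat p^{L_i})$ (parallel forced
paths of lengths $L_i$), non-predicted pairs incident to flagged vertices
are forbidden, and the remaining candidate pairs are indexed (`e_maybe`).
A candidate solution is a subset of those indices; its fitness is the
number of core pairs whose candidate connectivity (500 Monte-Carlo
samples by default, exact for tiny instances) falls within $\delta$ of the
observation. Parents are selected with probability proportional to
fitness above the population minimum, recombined at a random balanced cut
that never splits a contracted dense region, mutated at a rate of about 5%
of current edges (deletions and insertions balanced), and greedily
repaired to stay connected within each block.

## Numerical choices

* **Family-wise detection bands.** $\delta$ is a *per-entry* 95%
  half-width, but the cut-edge conditions compare $O(n^2)$ entries
  simultaneously; a per-entry band would therefore miss about 5% of true
  cut edges by construction. Detection instead uses
  $\max(\delta,\,4.5\sigma)$ for the probe condition and
  $\max(3\delta,\,5.5\sqrt{3}\,\sigma)$ for the product condition, where
  $\sigma = 1/(2\sqrt{n})$ is the worst-case per-entry standard deviation
  and $\sqrt 3$ propagates error through three estimated factors. These
  choices give family-wise coverage across hundreds of simultaneous
  comparisons. Exact matrices use machine-epsilon bands.
* **Candidate ordering.** Qualifying cut-edge pairs are probed in order of
  $|M(u,v) - \hat p|$ (ties lexicographically), so pairs matching the
  survival probability most closely — true bridges — win over hub pairs
  whose connectivity lands near $\hat p$ by coincidence.
* **Degree-2 ties.** On an exact matrix, more than two entries tied at the
  row maximum is a genuine ambiguity (a star center) and the vertex is
  rejected. On sampled matrices near-ties are expected whenever a degree-2
  vertex sits next to well-connected hubs, so the two largest entries are
  taken deterministically; this trades a few wrong-neighbor flags (the
  observed false-discovery rate stays in the 10–20% range at desk scale)
  for near-zero false-negative rates.
* **Direct-edge plausibility.** Under the model a direct edge forces
  $P(u,v) \ge \hat p$, so core pairs observed well below $\hat p$ are ruled
  out of the search space (re-admitted only if a block would otherwise be
  unconnectable).
* **GA control.** Fitness uses one common-random-number seed block for the
  whole run, so fitness values are comparable across generations and the
  running best is never an artifact of a lucky draw. Elite ordering and
  best-ever updates break fitness ties towards fewer edges. Elitism keeps
  the 5 best candidates, making the best-fitness history non-decreasing.
  The generation budget defaults to 200 but desk-scale analyses use
  40 generations with a population of 200.

## The synthetic generators

`generate_pam()` grows a preferential-attachment network from a single
edge, each new vertex attaching 1–2 edges (uniformly, expected attachment
factor 1.5) to degree-proportional targets; at $n = 1000$ this yields the
sparse, clique-free scale-free graphs used as ground truth. Because a new
vertex never adds more than two edges, these graphs cannot contain any
clique beyond a triangle — which makes them a specificity control for the
dense-region detector. `generate_dm()` duplicates degree-proportionally
chosen vertices, retaining each copied edge with probability 0.5 and never
linking the duplicate to its parent; it produces the clique-rich
counterpart. Under this degree-proportional rule the duplication model's
mean degree drifts upward as the network grows (redrawing zero-retention
steps alone guarantees that), so at $n = 1000$ these graphs are several
times denser than the preferential-attachment ones; they stress-test the
dense-region machinery rather than match a particular edge count.
`generate_fixture()` supplies the deterministic cases (paths, cycles,
cliques, random trees, planted cliques) used across the test suite.

What the generators emulate is the *model*, not real data: uniform
survival probability, independent edge failures, fully simultaneous
interactions, and a complete all-by-all bait coverage. Real AP-MS data
violates each of these (non-uniform interaction strengths, correlated
failures within complexes, partial tagging coverage, abundance noise far
from binomial), so error rates measured on these benchmarks are lower
bounds for what to expect on biological matrices.

## The AP-MS front end

Peptide counts are biased towards long proteins, so each bait→prey count
is divided by the prey's sequence length. The two directions of a pair are
averaged, and the symmetrized ratio $R$ maps to a connectivity estimate
through a logistic curve $1/(1 + e^{-(R - \alpha)/\beta})$ with the shipped
defaults $\alpha = 2.8921$, $\beta = -0.6318$ (fitted against the
simulated connectivity distribution of a gold-standard yeast binary
network via a chi-square histogram distance; `fit_logistic_params()`
refits on demand). Two quirks deserve a note. First, the shipped
$\beta < 0$ makes the transform *decreasing* in the normalized count,
which looks inverted relative to the model's intuition; the transform
keeps the fitted parameterization as shipped, and the sign is exposed for
configuration. Second, pairs never observed together map to connectivity
0 rather than to the logistic value at $R = 0$ (≈0.99 under the defaults):
an unobserved pair carries no evidence of connection, and the logistic
value at zero would claim near-certain connectivity.

## Scale of the shipped analyses

The test-suite benchmarks run on one CPU in minutes: 1-cut detection on a
200-vertex preferential-attachment network sampled at 20,000 realizations
(recovering the 1-cut set exactly), and an end-to-end comparison on a
150-vertex network, where the three-phase pipeline is held to ≤30%
overall FDR/FNR and must beat pure randomized hill-climbing. These are
deliberate scale-downs of the full 1000-vertex experiments with
multi-hour search budgets that the method is designed for; the genetic algorithm's share of the error
budget grows as the instance shrinks, because the hard core makes up a
larger fraction of a small network.

## Known limitations

* The genetic algorithm's fitness landscape on hard cores is a needle:
  the true graph scores near the maximum, but candidates missing 30% of
  its edges can score near zero, while overconnected candidates retain
  partial credit. At desk-scale budgets the search therefore settles on a
  plateau of roughly correct density rather than the exact core topology;
  reconstruction of the hard core carries error rates around 50% or more,
  an intrinsic difficulty of the hard core rather than a
  budget artifact.
* Degree-3-and-higher vertices have no matrix characterization here; they
  are resolved only by the genetic algorithm.
* The clique-count recurrence `gamma_connected()` is exact up to
  $n = 10$ (beyond that the counts exceed exact double-precision integer
  range, and no arbitrary-precision backend is required by anything the
  package computes).
* All guarantees are relative to the generative model; none of the
  assumptions (uniform $\hat p$, independence, simultaneity) survive
  contact with real lysates unscathed.
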