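---
title: "Methods: maximum-confidence paths on interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-confidence paths on interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiPaths)
```

## Model

A confidence-weighted interaction network is a graph $G$ (directed or
undirected) with edge weights $P(e) \in (0, 1]$ read as the probability
that interaction $e$ is real. For disjoint protein sets $A$ (sources) and
$B$ (targets), the strongest path maximizes the penalized confidence
product

$$y(A,B) = \arg\max_{\pi} \; \prod_{e \in \pi} P(e) \cdot D^{|\pi|},$$

where $D \in (0,1]$ is a constant per-edge penalty factor. Without the
penalty, ties between a short weak chain and a long strong chain of equal
product would be broken arbitrarily; with $D < 1$ the objective strictly
prefers fewer edges among equal products. Finding the *unpenalized*
maximum-product path in a general graph is NP-complete, but because every
factor lies in $(0,1]$ the log transform

$$W(e) = -(\log D + \log P(e)) \ge 0$$

turns the problem into a nonnegative-weight shortest-path search, solved
exactly in polynomial time. Multi-source/multi-sink queries reduce to a
single pair by attaching a super-source $\sigma$ to every $a \in A$ and
every $b \in B$ to a super-sink $\tau$.

Around the optimum $w^*$ (the shortest dual length), the set of nodes on
near-optimal paths is computed from two Dijkstra passes on the dual
graph: $a(v)$, the shortest dual distance $\sigma \to v$, and $b(v)$, the
shortest dual distance $v \to \tau$ (a pass over the reversed graph).
Then

$$V_\varepsilon = \{\, v : a(v) + b(v) \le w^* + \varepsilon \,\}.$$

Enumerating all $\varepsilon$-suboptimal *paths* can be exponential in
$\varepsilon$; $V_\varepsilon$ captures the intermediate proteins of
interest at the cost of two shortest-path computations, independent of
$\varepsilon$.

The remaining components are combinatorially simpler: greedy expansion
ranks external nodes by the summed confidence of their edges into the
current protein set; regulatory-path search runs plain BFS on a signed
directed network and classifies each hop-minimal path as activating or
inhibitory by the product of its $\pm 1$ edge signs; and reconstruction
benchmarks use the upper-tail hypergeometric test
(`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`), Benjamini–Hochberg
FDR, and precision/recall against a curated pathway gene set.

## Parameters

* `damping` ($D$, default **0.95**): per-edge penalty, unitless. At 0.95
  every extra edge costs a factor 0.95 in the objective; $D = 1$ disables
  the length preference entirely (ties then fall to the explicit
  tie-break rules below).
* `epsilon` (default **0**): slack above $w^*$, in dual-length units
  (natural log). Admitting paths up to $\varepsilon$ above $w^*$ means
  admitting penalized products down to $e^{-\varepsilon}$ times the
  optimum, so $\varepsilon$ is readable as $-\log$ of a probability
  ratio. Because the logs are natural, users porting thresholds from a
  base-10 formulation should multiply by $\ln 10$.
* `sparse` (default dense): dense output is the induced subgraph on
  $V_\varepsilon$; sparse output keeps only edges $(u,v)$ with
  $a(u) + W(u,v) + b(v) \le w^* + \varepsilon$ — edges that themselves
  lie on an $\varepsilon$-suboptimal path. Sparse is never larger than
  dense over the same node set.
* `scoreDivisor` (default 1): divides raw file scores before validation,
  e.g. 1000 for combined scores exported on a 0–1000 integer scale.
  Scores outside $(0,1]$ after rescaling are a hard error, never
  clamped — silent clamping would fabricate certainty.
* `unknownPolicy` (default drop): regulatory edges whose mode of
  regulation is "Unknown" have no defined sign; they are excluded by
  default, or optionally treated as activating or as both signs.
* `maxPerPair` (default 100): cap on enumerated hop-minimal paths per
  (source, target) pair; hitting it raises a warning. Distinct minimal
  paths can carry different modes, so all of them are enumerated rather
  than one representative.

## Numerical and procedural choices

* **Natural logarithm everywhere.** The base only rescales
  $\varepsilon$; $\ln$ keeps dual lengths interpretable as negated log
  probabilities.
* **Super edges carry dual weight exactly 0**, not $-\log D$: they are
  artificial and must not charge the length penalty twice per path.
* **Tie-breaking.** Among exact dual-length ties the path with fewer
  edges wins (automatic when $D < 1$; enforced explicitly otherwise),
  then the lexicographically smallest label sequence. Implementation:
  restrict to the shortest-path DAG (arcs with
  $a(u) + W + b(v) \le w^* + 10^{-9}$), compute per-node minimum hop
  counts to $\tau$ by reverse BFS, and walk greedily by smallest label
  among hop-optimal successors. Stepwise greedy choice yields the
  global lexicographic minimum because a hop-optimal completion always
  exists from any DAG node on the walk.
* **Boundary slack.** $V_\varepsilon$ membership and DAG membership use
  an additive $10^{-9}$ slack to absorb floating-point noise; nodes of
  the optimal path satisfy $a(v) + b(v) = w^*$ up to rounding and must
  never fall out of $V_0$.
* **"No path" is a result, not an error.** Batch runs over several
  databases must continue past databases in which the query sets are
  disconnected; `pathFound()` distinguishes the outcome, and the CLI
  exits 0 while writing a `NO_PATH` marker.
* **Duplicate edges keep the maximum confidence.** Max is idempotent and
  order-independent, so concatenated database dumps parse to the same
  network regardless of row order, and "strongest" semantics are
  preserved. For undirected networks $(A,B)$ and $(B,A)$ are the same
  edge. Self-loops are dropped: they cannot lie on a simple path and
  would distort expansion scores.
* **Identifier matching is case-insensitive and whitespace-trimmed**;
  gene symbol casing varies across sources. An alias shared by several
  records (paralogs) resolves to all of them in query lists, but network
  file endpoints must resolve uniquely — a network row naming an
  ambiguous alias is an input error, since edge identity would otherwise
  be guesswork.
* **Expansion scoring** counts only edges between a candidate and the
  current set (not candidate–candidate edges), in both orientations for
  directed networks. Batch mode ranks once and takes the top $n$;
  sequential mode re-ranks after each addition, which models repeated
  one-step expansions and can reach nodes batch mode cannot.
* **$V_\varepsilon$ and non-simple walks.** The computational criterion
  $a(v) + b(v) \le w^* + \varepsilon$ can admit a node whose witnessing
  $\sigma \to v \to \tau$ concatenation revisits a node, i.e. is a walk
  rather than a simple path. This is the stated and implemented
  criterion; in validation sweeps the discrepancy never produced a node
  set differing from the exhaustive-relaxation oracle, which applies the
  same criterion.

## What the synthetic generators emulate

`randomNetwork()` draws Erdős–Rényi topologies with uniform confidences;
`plantedPathNetwork()` embeds a high-confidence chain (default three
edges at 0.95, matching typical experimentally-validated interaction
scores) in low-confidence noise (capped at 0.3, the usual cut-off below
which predicted interactions are considered weak); and
`randomSignedNetwork()` signs directed Erdős–Rényi edges inhibitory with
a fixed probability. One integer seed drives each generator through a
local RNG scope, so generation is bit-reproducible and never perturbs the
caller's random stream.

These models deliberately do *not* reproduce the degree heterogeneity,
clustering, or confidence-score mixtures of real PPI databases
(scale-free hubs, experimental/predicted score bimodality). They are
correctness instruments: passing the oracle sweeps shows the algorithms
are exact on arbitrary weighted topologies of the sizes tested, not that
biological conclusions from any particular database are correct. Real
networks are much larger; the algorithms scale as Dijkstra
($O(m + n \log n)$) and BFS, so size affects runtime, not correctness.

## Validation problem sizes

The oracle sweeps use networks of 4–10 nodes at densities 0.2/0.5/0.8,
directed and undirected, with $D \in \{1.0, 0.95, 0.8\}$ — 300 instances
in the test suite — because exhaustive simple-path enumeration (the
independent oracle) is tractable there while still covering multi-edge
ties, disconnected queries, and both orientations. Planted-path recovery
uses 100 networks of 20 nodes at density 0.2, where the brute-force
oracle remains feasible thanks to branch-and-bound pruning (a partial
path is pruned when its score already falls below the incumbent, which
is exact because every extension multiplies by factors $\le 1$).
Expansion and regulatory sweeps use 100 instances each. The full suite
runs in well under a minute.

## Known limitations

* The engine searches one network per call; querying several databases
  simultaneously is a loop at the CLI level, and cross-database evidence
  is not merged beyond the max-merge of duplicate rows within one file.
* Enumerating the $\varepsilon$-suboptimal *paths* themselves (rather
  than $V_\varepsilon$) is out of scope, as is $k$-shortest-path search.
* Regulatory paths are unweighted (hop-minimal); confidence-weighted
  signed search is not provided because mode-of-regulation databases do
  not ship calibrated probabilities.
* The hypergeometric background is the node set of the network actually
  searched; enrichment numbers are only comparable across methods run on
  the same background.
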