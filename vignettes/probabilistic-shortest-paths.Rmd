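---
title: "Counting shortest paths exactly in probabilistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting shortest paths exactly in probabilistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probnet)
```

## The model

A probabilistic network attaches to each edge an independent presence
probability `p` in `(0, 1]`; a probability of exactly 0 is rejected at
construction, since an impossible edge is expressed by omitting it. The
network is semantically a product distribution over the `2^m` deterministic
instances, with instance probability given by the product rule (present
edges contribute `p`, absent edges `1 - p`). Edge independence is the one
substantive modelling assumption everything below inherits: confidence
scores from interaction databases are treated as marginal presence
probabilities with no correlation structure.

The central object is the random variable `B(s~t)`, the number of shortest
`s`–`t` paths across instances. Its support is `0, ..., k*`, where `k*` is
the largest number of simple paths sharing one length: all of them, but no
more, can be shortest simultaneously. A pair with no path at all has the
point-mass distribution at 0 and bypasses the machinery.

## The algorithm and its numerical choices

`count_shortest_paths()` enumerates all simple paths between the pair by
recursive depth-first search with neighbours expanded in lexicographic
node-id order, builds the path–edge bipartite graph, and multiplies one
two-term edge polynomial per distinct edge. Three rules keep the expansion
exact but small:

* **Collapse.** Once the last polynomial touching a path variable has been
  multiplied in, the variable's exponent is final: a full exponent means the
  whole path is present and the variable becomes a length marker; any
  smaller exponent means the path is broken and the variable is dropped.
* **Early select.** Paths are processed in ascending length groups. At the
  end of group `r`, any term carrying a marker of length `r` is retired as
  `y^j` (`j` markers of the group length), because no longer path can beat a
  realised length-`r` path. Retiring early is exact: the unmultiplied edge
  polynomials each sum to one, so they could only redistribute — never
  change — the retired coefficient. The package also ships a multiply-all
  reference (`naive_count_shortest_paths()`, written in the literal
  term-by-term operator algebra of `poly_term()`, `collapse_term()`,
  `select_term()`), and the test suite asserts both routes agree to
  `1e-12` on hundreds of random networks.
* **Merging.** Terms with identical signatures are merged after every
  multiplication. The production engine exploits the fact that a path is
  "alive" in a term precisely when every one of its already-multiplied edges
  is present, in which case its exponent is determined; signatures therefore
  reduce to (alive path set, marker set), which is the same algebra in a
  smaller key space. Terms whose every path is broken are folded into the
  disconnection mass immediately.

Arithmetic is plain floating point — probabilities are empirical, so exact
rationals would suggest spurious precision — and each distribution is checked
against a mass-conservation guard of `1e-6`; the observed drift on the test
suite is at machine precision (`~1e-15`). Exactness is validated externally
against `oracle_sp_distribution()`, which enumerates every instance and
counts via the indicator construction (a path counts when it is present and
no strictly shorter co-present path exists), itself cross-checked against
BFS geodesic counting.

Exactness requires the *complete* simple-path set of a pair, so the caps
(`max_paths`, default `1e5`, and the term-pool cap `max_terms`, default
`5e5`) are hard errors rather than truncations: a silently truncated path
set would corrupt the distribution. Degenerate inputs are handled explicitly:
`p = 1` edges drop their zero-coefficient absent term; zero-path pairs return
the point mass at 0; source equal to sink is an error.

## Expected betweenness

Edge betweenness generalises by crediting, whenever a term retires with `j`
equal-length shortest paths and coefficient `alpha`, each edge of each such
path with `alpha / j` — the equal-split rule. Each pair's total credit is
normalised by the probability that the pair is connected at all (pairs that
can never connect contribute nothing, which is also what keeps the
normalisation well defined), and the edge total is finally divided by the
edge's own presence probability. That last rescaling is applied exactly as
defined, with a documented quirk: an isolated edge of probability `p` gets
betweenness `1/p` rather than 1, because the connectivity normalisation has
already conditioned on presence once. We deliberately do not "fix" this; in
the deterministic limit (`p = 1` everywhere) the definition reduces to
classical equal-split edge betweenness, which the tests verify against
igraph. Node betweenness has no separate definition in the underlying
formulation; the package mirrors the edge aggregation, crediting interior
nodes of contributing paths and omitting the presence rescaling (nodes are
certain). This choice uniquely reproduces classical node betweenness in the
deterministic limit.

Per pair, the distribution and all edge/node credits are extracted in a
single polynomial run (`pair_edge_contributions()`); betweenness for the
whole network loops over unordered pairs (ordered for directed networks).

## Expected modularity and community detection

The expected Newman modularity of a partition is computed per community: its
edges split into *within*, *boundary* and *outside* classes, each class
yields the distribution of its number of present edges by iterative
convolution of `(q_i, p_i)` factors (quadratic in the class size), and since
the classes are disjoint the joint coefficient is the product of the three
marginals. A configuration with `i` within, `j` boundary and `k` outside
edges contributes `i/m - ((2i + j)/(2m))^2` with `m = i + j + k`; the
all-empty configuration contributes 0 — the choice is ours to make (the
expectation is otherwise undefined there), 0 being the unique finite value
and the one that preserves the deterministic limit. The result is verified
against full-instance enumeration on small networks and against the direct
deterministic evaluation at `p = 1`.

`detect_communities()` follows the divisive recipe: remove the edge of
highest expected betweenness, recompute, record the connected components of
the surviving topology at every level, and return the level with maximal
expected modularity — always evaluated against the *original* probabilistic
network, since the partition quality is defined by the expectation over its
instances. Components are taken on the surviving topology with remaining
edges treated as present; the uncertainty enters through the betweenness
ranking and the modularity score. Ties in betweenness are broken by
lexicographic edge id so runs are deterministic. Modularity is an undirected
notion; directed input is symmetrised for this purpose with a warning.

## The synthetic benchmark

`generate_lfr()` emulates the LFR benchmark family: truncated power-law
degrees (exponent 2 by default) with the lower cut-off calibrated
numerically so the mean degree hits the request, truncated power-law
community sizes (exponent 1), a mixing parameter `mu = 0.2` splitting each
node's stubs between its own community and the rest, and stub-matching
wiring with self-loops and duplicates rejected. Probabilities come from
three models: identical (all `0.5`), uniform on `(0, 1]`, and normal with
mean `0.5` and standard deviation `0.1`–`0.3`, truncated to `(0, 1]` by
rejection resampling — truncation rather than clipping, to avoid probability
atoms at the boundaries. What the generator does *not* emulate: degree-
community size correlation constraints of the full LFR rewiring procedure,
correlated edge probabilities, and any biological structure beyond
communities; passing benchmarks on these networks demonstrates correctness
and the failure modes of the baselines, not performance on real interaction
data.

The counting benchmark (`run_counting_benchmark()`) draws replicate
networks, takes the exact expected count as truth and compares three
baselines: *binary* (count on the full topology), *threshold* (edges with
`p` strictly above the threshold, default `0.6`; skipped under the identical
model where it keeps all or none of the edges) and *sampling* (mean BFS
count over 1000 Bernoulli instances, shared across a network's pairs).
Pairs with zero true count are excluded — the relative error
`|f - f*| / f*` is undefined there; medians are taken over a network's
included pairs and then over replicate networks, with means reported
alongside (the pair-level aggregation choice is ours and both are emitted).

Two protocol choices keep the harness desk-scale, and both are reported in
the output rather than hidden. First, the benchmark runs on *directed*
networks (each generated edge given a random orientation): the number of
simple paths between a pair of an undirected sparse benchmark graph explodes
combinatorially (beyond `2 * 10^5` already at 50 nodes and mean degree 3),
which makes exact full-path counting infeasible there for *any*
implementation of this algorithm, while directed instances keep path counts
in the hundreds. Second, each network contributes a seeded subsample of its
topology-reachable pairs (40 per network in the shipped acceptance runs),
and pairs whose path set or term pool overflows the caps
(`max_paths = 3000`, `max_terms = 5e4` by default in the harness) are
excluded and counted in `skipped`. The qualitative result — median relative
error of binary far above threshold, threshold above sampling — is stable
across sizes 50–250 and seeds under these conditions.

## Sizes used by the shipped checks

The test suite verifies oracle equivalence on 200 random networks of 4–10
edges (where full enumeration is exact and fast), deterministic limits on
random 7-node graphs, modularity equivalence on 25 random partitions, and
the benchmark ordering on directed LFR-style networks of 50, 100 and 250
nodes with 10 replicates and 40 sampled pairs each, 1000 samples for the
sampling baseline. `scripts/acceptance.R` recomputes the same quantities
from scratch under a caller-supplied seed.

## Known limitations

* Path enumeration is exponential in the worst case; the caps make the
  failure explicit rather than silent. Undirected, cyclic, locally dense
  regions are the hard case.
* Only the *number* of shortest paths is tracked, not their length
  distribution; the select operator discards the length after choosing the
  minimum (a length-resolved variant would replace `y` by per-length
  markers).
* Edge probabilities are assumed independent; correlated uncertainty is out
  of scope.
* Expected-betweenness community detection recomputes all-pairs
  distributions after every removal and is intended for networks of tens of
  nodes, matching its role as a quality reference rather than a
  throughput tool.
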