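# probnet

Exact shortest-path counting and community detection in **probabilistic
networks** — graphs whose edges carry independent presence probabilities, as
produced by protein-interaction databases that score each interaction with a
confidence value.

## The problem

A probabilistic network `G = (V, E, P)` with `m` uncertain edges is a compact
description of `2^m` deterministic networks ("possible worlds"): each edge
`e_i` is present with probability `p_i` and absent with `q_i = 1 - p_i`,
independently. The number of shortest paths between two nodes `s` and `t` is
then a random variable `B(s~t)`: a longer path becomes *the* shortest path in
worlds where all shorter paths are broken. Counting shortest paths is a basic
primitive behind centrality, communication-cost and community-structure
analyses, and the common practice of first flattening the probabilistic
network (keeping every edge, thresholding on probability, or sampling) and
then counting on the flattened graph is badly biased, because the count is a
nonlinear functional of the edge indicators.

## The method

`probnet` computes the exact law of `B(s~t)` without enumerating the
`2^m` worlds:

1. All simple `s`–`t` paths `H_1, ..., H_K` are enumerated on the topology
   and arranged in a path–edge bipartite graph.
2. Each distinct edge `e_j` contributes a two-term **edge polynomial**
   `Z_j = p_j * prod_{H_i ∋ e_j} x_i + q_j` over path-indicator variables.
3. The product of all edge polynomials is expanded with two operators that
   keep the expansion small: **collapse** replaces a path variable at full
   exponent by a path-length marker `t_l` (all of that path's edges are
   present) or deletes it (the path is broken), and **select** converts the
   smallest-length markers of a term into the shortest-path marker `y`,
   retiring the term. Processing path-length groups in ascending order lets
   select fire early; the retired coefficients are exactly
   `Pr(B(s~t) = k)` for `y^k`.

On top of the distribution the package computes, all exactly:

- **expected edge / node betweenness** — equal-split shortest-path credit
  aggregated over node pairs, each pair normalised by its connectivity
  probability, edges rescaled by their own presence probability
  (`f(e) = Exp(B_e) / p_e`);
- **expected modularity** of a partition via per-community *xyz*-polynomials
  (within / boundary / outside edge-presence laws), and divisive
  **community detection** that repeatedly removes the edge of highest
  expected betweenness and keeps the level of maximal expected modularity;
- baseline transforms (binarise / threshold / Bernoulli sampling), an
  LFR-style synthetic benchmark generator with planted communities and three
  edge-probability models, a brute-force enumeration **oracle**, and a
  benchmark harness comparing the baselines against the exact expectation.

## Worked example

The five-node, seven-edge example network has five simple paths between `a`
and `d` (lengths 1, 3, 3, 4, 4), so between 0 and 2 of them can be shortest
simultaneously:

```r
library(probnet)
net <- toy_network()          # edges (a,d) (b,c) (b,d) (a,c) (c,e) (b,e) (e,d)
d <- count_shortest_paths(net, "a", "d")
tidy(d)
#> # A tibble: 3 × 2
#>       k  prob
#>   <int> <dbl>
#> 1     0 0.267
#> 2     1 0.543
#> 3     2 0.191
expected_count(d)
#> [1] 0.9237376
connectivity_probability(d)
#> [1] 0.7332256
```

With the bundled probabilities the pair is connected with probability 0.733
and carries on average 0.92 shortest paths; the mass at `k = 2` (0.191) is
the probability that both length-3 paths are realised while the direct edge
is absent. The same distribution falls out of brute-force enumeration of all
128 worlds (`oracle_sp_distribution(net, "a", "d")`), which is how the test
suite verifies the algebra.

Community detection on two strong triangles joined by one weak edge:

```r
res <- detect_communities(two_triangles_bridge())
glance(res)
#> # A tibble: 1 × 4
#>       k     Q best_step n_steps
#>   <int> <dbl>     <int>   <int>
#> 1     2 0.471         1       7
tidy(res)                      # the two triangles, exactly
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/probnet.R count --network inst/extdata/toy_network.tsv \
    --source a --sink d
```

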