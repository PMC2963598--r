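# dcbnet

Exhaustive discovery of **densely connected biclusters**: gene modules that
are simultaneously well connected in an interaction network (PPI/GI) and
co-expressed across enough conditions of an expression compendium. The
package is aimed at systems biologists who want *all* such modules — not a
heuristic sample — together with the statistics to rank them and the
GO-based metrics to assess a module collection.

## The model

The input is a *profile network* `G = (V, E, p)`: an undirected graph over
genes where each gene carries a profile `p(v)` of log fold-changes over a
shared condition list. For thresholds `(γ, ε, d_min)`, a gene set `S` with
condition set `D` is a **densely connected bicluster (DCB)** when

* the induced subgraph is **connected**,
* its **density** `|E(S)| / C(|S|, 2)` is at least `γ`, and
* `D` holds at least `d_min` conditions in which all genes of `S` have
  observed values within `ε` of each other.

`enumerate_dcbs()` returns exactly the maximal DCBs by a breadth-first
lattice traversal that grows size-`k+1` candidates only from size-`k` DCBs.
For `γ ≥ 0.5` the DCB constraint is *loosely anti-monotone* — every DCB
contains a DCB one size smaller — so the traversal is provably exhaustive;
`brute_force_dcbs()` is the naive oracle that verifies this on small
instances and serves `γ < 0.5`. Downstream, `merge_modules()` collapses
heavily overlapping DCBs into core–attachment modules, `rank_modules()`
scores modules against a truncated-normal co-expression null (2000 sampled
connected subnetworks) and a hypergeometric density null, `filter_ranked()`
removes redundant modules top-down, and `evaluate_modules()` computes the
assessment metrics ER, COV, IC and OMPSDF from gene–GO annotations.

## Worked example

Plant two dense, co-expressed modules in a random 60-gene background and
recover them:

```r
library(dcbnet)

plants <- list(list(size = 5, density = 0.8, subspace_size = 4),
               list(size = 6, density = 0.7, subspace_size = 4))
spec <- plant_spec(n_genes = 60, edge_p = 0.04, n_conditions = 8,
                   plants = plants, band_width = 0.5, seed = 11)
sim <- generate_planted(spec)
sim$network
#> profile_network: 56 genes, 88 interactions, 8 conditions (0% missing)

params <- dcb_params(gamma = 0.6, epsilon = 0.5, d_min = 3)
mods   <- enumerate_dcbs(sim$network, params, min_size = 3)
merged <- merge_modules(mods, net = sim$network)
merged
#> dcb_module_set with 2 module(s)
#>   size density provenance n_conditions                   genes
#> 1    6     0.8 enumerated            4 g06,g07,g08,g09,g10,g11
#> 2    5     0.8 enumerated            4     g01,g02,g03,g04,g05

ranked <- rank_modules(merged, sim$network, epsilon = 0.5,
                       n_samples = 2000, seed = 11)
as.data.frame(ranked)[, c("size", "p_coexpression", "p_density", "overall_rank")]
#>   size p_coexpression    p_density overall_rank
#> 1    6              0 2.280578e-13          1.0
#> 2    5              0 3.413884e-09          1.5

score_recovery(filter_ranked(ranked), sim$truth)
#> $jaccard
#> [1] 1 1
#> $n_exact
#> [1] 2
```

Both planted modules are found exactly (Jaccard 1), with 4 witnessing
conditions each; the p-values say a random connected subnetwork of that
size essentially never reaches 4 co-expressed conditions
(`p_coexpression ≈ 0`) or that edge count (`p_density` down to `1e-13`).

The same pipeline is available from the shell via the shipped script
(`inst/cli/dcbnet`): subcommands `simulate`, `preprocess`, `enumerate`,
`oracle`, `merge`, `rank`, `filter`, `evaluate`, composing through a
documented module TSV format.

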