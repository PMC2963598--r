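---
title: "Dense, co-expressed module discovery with dcbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense, co-expressed module discovery with dcbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcbnet)
```

## The model

dcbnet works on a *profile network*: an undirected gene interaction graph
(protein--protein and genetic interactions pooled into one edge set) in which
every gene additionally carries an expression profile -- a vector of log
fold-changes over a shared, ordered list of conditions, with missing values
allowed. A candidate module is a gene set $S$ with an associated condition
set $D$, and $S$ is a **densely connected bicluster (DCB)** under parameters
$(\gamma, \varepsilon, d_{\min})$ when

1. the subgraph induced by $S$ is **connected**;
2. its **density** -- edges present divided by $\binom{|S|}{2}$ -- is at
   least $\gamma$;
3. the genes of $S$ are **co-expressed** in at least $d_{\min}$ conditions:
   $D$ collects the conditions where every gene of $S$ has an observed value
   and the spread ($\max - \min$, equivalently the largest pairwise
   difference) is at most $\varepsilon$.

The package returns the *maximal* DCBs: those whose gene set is not a strict
subset of another DCB's. Everything downstream (merging, ranking,
assessment) consumes these modules.

Two modelling conventions are worth stating explicitly. A condition with a
missing value for any member gene never witnesses co-expression -- this is
the conservative reading, and it matters for sparse human fold-change
matrices where missingness is substantial. And the co-expression check is
implemented as a per-condition spread test, which is algebraically identical
to requiring all pairwise differences to stay within $\varepsilon$ but costs
$O(|S|)$ rather than $O(|S|^2)$ per condition.

## Exhaustive enumeration and why $\gamma \ge 0.5$

`enumerate_dcbs()` organizes all connected subnetworks in a lattice in which
a subnetwork's children are its one-gene extensions, and traverses it
breadth-first: level 2 holds every edge whose endpoints co-express in at
least $d_{\min}$ conditions, and level $k{+}1$ candidates are generated only
as one-neighbor extensions of level-$k$ DCBs. The traversal is exhaustive
because the DCB constraint is *loosely anti-monotone* for
$\gamma \ge 0.5$: every DCB of size $k{+}1$ contains at least one DCB of
size $k$ (one can always delete some vertex -- essentially a smallest-degree
one, with care for articulation points -- without breaking density or
connectivity, and co-expression is inherited by every subset). Below
$\gamma = 0.5$ that guarantee fails, and `enumerate_dcbs()` refuses rather
than silently returning an incomplete answer; `brute_force_dcbs()`, which
tests every induced subgraph and is deliberately naive, serves both as the
verification oracle and as the fallback for $\gamma < 0.5$ on small
networks (it is capped at 18 genes).

Maximality is decided by a global post-hoc subset check over all enumerated
DCBs rather than by "has no DCB child": a DCB two sizes larger need not
contain an intermediate DCB *through a particular subset*, so the local
child test could mislabel. The post-hoc check implements the definition
literally.

Edge pruning (`prune_edges()`, applied implicitly at level 2) removes every
edge whose endpoint pair co-expresses in fewer than $d_{\min}$ conditions.
This is sound -- the co-expression subspace is anti-monotone, so such a pair
can never sit inside any DCB -- and the test suite verifies on random
instances that pruning leaves the maximal-DCB set untouched.

## Merging into core-attachment modules

Interaction maps are incomplete and expression is noisy, so one functional
unit often surfaces as several heavily overlapping DCBs around a shared
dense core. `merge_modules()` repeatedly merges the pair with the highest
member overlap among those overlapping in at least `member_overlap` of
their gene sets *and* `subspace_overlap` of their condition sets, replacing
it by the gene union with the subspace intersection, until a fixpoint.
Design choices, each genuinely open:

* **Overlap denominator = smaller set** (default): a small module sitting
  almost wholly inside a larger one should merge; Jaccard is available via
  `overlap = "jaccard"`.
* **Merged subspace = intersection**: a union could contain conditions in
  which no pair of members co-expresses. The intersection can drop below
  $d_{\min}$; the merge is still performed (the refinement deliberately
  relaxes the constraints, which is also why merged densities may fall
  below $\gamma$) and reported via a message.
* **Defaults 0.75/0.75**: the thresholds are genuinely free parameters; 3/4
  member overlap is the smallest value at which two size-4 modules can
  share a triangle core, and runs should set both explicitly.
* Ties between equally overlapping pairs break lexicographically on the
  gene lists, and the input is canonically ordered first, so the fixpoint
  is deterministic and independent of input order (property-tested).

## Ranking and redundancy filtering

The exhaustive output is large by design; ranking reduces it to a
collection comparable with methods that emit few modules. Each module gets
two upper-tail p-values:

* **Co-expression**: the observed number of co-expressed conditions is
  compared against an empirical null built by sampling 2000 random
  *connected* subnetworks (uniform start gene in a large-enough component,
  then uniformly random neighbor extensions) and fitting a normal
  distribution truncated to $[0, C]$, $C$ the number of conditions, by
  maximum likelihood. The null is fitted per module size -- condition
  counts depend strongly on set size -- with a pooled mode behind a flag. A
  constant sample degenerates to a point mass, handled explicitly.
* **Density**: the probability that $\binom{k}{2}$ gene pairs drawn from
  the $\binom{n}{2}$ possible pairs of the network contain at least $m$ of
  its $|E|$ edges, i.e. a hypergeometric upper tail.

Both tails are upper because *more* co-expressed conditions and *more*
edges are the interesting direction. Modules are ranked on each criterion
separately (competition ranking; ties share the best rank) and ordered by
the average of the two ranks, with residual ties broken by size then gene
list. `filter_ranked()` then walks the list top-down and drops every module
whose genes are already covered by the union of the kept modules above it
-- reading "contained in the modules higher up" collectively; a
single-module containment mode exists behind a flag -- optionally stopping
after a top-$N$ collection.

## Assessment metrics

Given a gene-to-term table and term levels (shortest directed path from an
ontology root, computed by multi-source BFS over a child--parent table),
`evaluate_modules()` computes:

* **Basic statistics**: genes covered, module count, average module size,
  average (recomputed) density.
* **ER**, the share of modules enriched -- one-sided hypergeometric test
  against the post-filter dataset background, Benjamini--Hochberg corrected
  across all (module, term) tests of the run -- with at least one term of
  level $\ge 7$ ("level 7 or higher", i.e. inclusive).
* **COV**, the share of dataset-associated terms enriched in some module.
* **IC**, the mean over module genes of the fraction of a gene's terms
  enriched in a module containing it: partitioning methods can serve each
  gene at most one functional context, overlapping ones several.
* **OMPSDF**, the count of overlapping module pairs that share no enriched
  term at level $\le 3$ yet share a gene carrying two level-$\ge 7$ terms
  enriched one in each module only -- the configuration in which a shared
  gene demonstrably supports two different functionalities. Any partition
  scores 0, which the tests verify on constructed partitions.

The enrichment test, correction method and all three cutoffs (p < 0.05,
core level 3, deep level 7) are explicit configuration with those defaults;
published GO-tool internals vary, so results on real GO releases are
version- and method-dependent.

## The synthetic generator

`plant_spec()`/`generate_planted()` produce the benchmark instances the
test suite runs on: an Erdős–Rényi background (degree-preserving rewiring
available behind a flag) with planted gene sets, each wired as a random
spanning tree plus random extra edges up to exactly
$\lceil \text{density} \cdot \binom{k}{2} \rceil$ edges, and co-expressed
on a random condition subset by drawing member values uniformly within
$\pm\,\text{band\_width}/2$ of a per-condition center -- so the spread
constraint holds exactly, by construction. All other cells are independent
$N(0, \text{background\_sd})$ draws (default sd 2, a realistic log
fold-change scatter); `noise_sd` adds Gaussian perturbation to the
*planted* cells, so raising it progressively destroys the planted
co-expression and recovery degrades monotonically (tested on medians over
seeds). Missing values are masked outside planted cells at the configured
rate.

One subtlety is essential for the generator's contract: on a plant's
conditions, non-member values are redrawn until they lie more than
$1.5 \times \text{band\_width}$ from the plant's center. A background value
inside that guard zone can co-express with the plant's members, spawning
chance DCBs that overlap the plant heavily enough for the merge step to
absorb them -- at which point "exact recovery" is no longer a property of
the method but of the dice. With the guard, a noise-free instance recovers
every planted module exactly (Jaccard 1.0), deterministically across seeds.

What the generator does *not* emulate: scale-free interaction topology,
condition-correlated noise, and structured missingness. Passing recovery
tests therefore demonstrate algorithmic correctness on well-posed
instances, not performance on real compendia.

## Numerical and engineering choices

* Singleton density is defined as 1 (avoids 0/0; singletons are never
  reported, the convention only affects internal calls).
* Gene identifiers are opaque, case-sensitive strings; genes present in
  only one of the two inputs are dropped with a message.
* Condition indices are 1-based everywhere, including the module TSV.
* Module files store numbers at 17 significant digits so write/read
  round-trips are exact; records are written in canonical order (size
  descending, then lexicographic gene list), making all outputs
  byte-deterministic.
* The truncated-normal fit optimizes $(\mu, \log\sigma)$ by Nelder--Mead on
  the exact truncated log-likelihood; at the truncation bound the upper
  tail is exactly 1 (lower) and 0 (upper), and the p-value is monotone
  non-increasing in the observed count.
* `enumerate_dcbs(max_size = )` is an engineering safety valve; hitting it
  warns loudly because it voids completeness.

## Problem sizes in the test suite

The suite exercises oracle equivalence on 200 random instances of up to 12
genes and 6 conditions across $\gamma \in \{0.5, 0.6, 0.8\}$, planted
recovery on 100-gene backgrounds with five plants of sizes 4--8, and
ranking nulls with 2000 draws where parameter recovery is asserted (smaller
draw counts elsewhere, where only determinism and contracts are at stake).
These sizes were chosen so the whole suite completes in a couple of minutes
while still covering every code path at the scale where the brute-force
oracle is exact.

## Limitations

* Exhaustive enumeration below $\gamma = 0.5$ is served only by the
  brute-force oracle, which does not scale; the subroutines that would
  extend lattice completeness below 0.5 are out of scope.
* Edges are unweighted and undirected; interaction confidence scores are
  not modeled.
* The ranking null samples connected subnetworks uniformly by neighbor
  growth; degree-preserving rewiring nulls are a plausible alternative the
  package deliberately does not implement.
* On real GO data the assessment metrics depend on the annotation release
  and correction settings; they are comparative instruments, not absolute
  quality scores.
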