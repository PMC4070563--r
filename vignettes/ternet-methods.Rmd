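---
title: "Methods: ternary co-expression networks and promoter element discovery"
author: "ternet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ternary co-expression networks and promoter element discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternet)
```

# Scope and model

`ternet` reconstructs gene co-expression networks from *ternary*
differential-expression data and then interrogates the result at three
levels: global topology, densely connected modules, and shared promoter
k-mers that may explain a module's co-regulation.

The input model is deliberately coarse. Each gene in each condition is
coded +1 (called up-regulated), -1 (called down-regulated) or 0 (no
call). This encoding is natural when the primary data are per-condition
differential-expression gene lists rather than a normalized expression
matrix: lists from heterogeneous experiments can be merged without any
cross-platform normalization, at the cost of discarding magnitude
information. All inference in the package starts from a
`TernaryExpressionMatrix`.

# Network construction

## Linear: Pearson correlation

`pearsonAll()` computes all-pairs Pearson correlation between ternary
profiles. Two constructions turn similarities into a network:

* `pccThresholdNetwork(s, t)` keeps an edge where the *signed*
  correlation is at least `t` (default 0.9). Anti-correlated pairs do
  not form edges under the signed rule; pass `absolute = TRUE` to rank
  by magnitude. Every gene remains a node, so the node count does not
  depend on the threshold.
* `mknnNetwork(s, k)` applies a modified mutual k-nearest-neighbour
  rule. A gene's k-list contains its k-1 highest-correlation partners
  *plus every gene tied at the k-th value*: with coarse ternary data,
  exact correlation ties are common, and two genes with equal
  correlation are equally valid neighbours, so truncating a tie would
  be arbitrary. An edge requires mutual list membership. Edge counts
  are non-decreasing in k (a property the test suite checks).

Zero-variance genes have undefined correlation; they are reported `NA`,
never form edges, and stay in the network as isolated nodes.

## Non-linear: Kraskov mutual information

`kraskovMiAll()` estimates mutual information with the first Kraskov
k-nearest-neighbour estimator (neighbourhood size `k_neighbors = 3` by
default): for each point the distance `eps` to its k-th neighbour is
taken in the max-norm on (x, y), and

I(X, Y) = psi(k) + psi(N) - < psi(nx + 1) + psi(ny + 1) >,

where `nx`, `ny` count points strictly within `eps` along each
marginal. The estimator assumes continuous data; ternary profiles are
massively tied, so i.i.d. Gaussian jitter of scale `jitter_sd = 1e-12`
(seeded, reproducible) is added first. The jitter is twelve orders of
magnitude below the data spacing: it breaks ties without moving any
point relative to the structure. On a bivariate Gaussian with rho =
0.9 and N = 2000 the estimate falls within 0.1 nats of the closed form
-log(1 - rho^2)/2 = 0.830, which the acceptance suite verifies.

Three post-processing operators are provided, all operating on the full
MI matrix with decisions taken simultaneously (so gene order is
irrelevant):

* `aracnePrune()` applies the data-processing inequality: in every
  gene triple the weakest edge is removed, with an additive epsilon or
  a multiplicative tau tolerance.
* `clrTransform()` converts each MI value into per-gene background
  z-scores and combines the two directions as sqrt(zi^2 + zj^2).
* `mrnetBuild()` scores pairs by forward maximum-relevance
  minimum-redundancy selection per target gene.

`fractionThresholdNetwork(s, fraction)` then keeps edges whose weight
reaches `fraction` times the maximum off-diagonal weight. Unlike the
PCC constructions, isolated genes are dropped here: the max-fraction
rule is used for MI-derived scores whose absolute scale is not
comparable across datasets, and reporting a node count that tracks the
surviving structure is the convention the downstream summaries expect.

# Topology battery

`topologyReport()` bundles: degree distribution with a log-log OLS
power-law fit, local clustering coefficients and their degree-grouped
curve, shortest-path distribution and component-restricted closeness,
Brandes betweenness, shared-neighbour distribution, neighbourhood
connectivity, topological coefficients, connected components, density,
hub extraction (`hubs()`, default degree >= 50) and top-betweenness
extraction (`topBetweenness()`, default top 90, ties at the cutoff
included). Standard metrics are delegated to `igraph`; every metric is
also validated against brute-force enumeration oracles in the test
suite (exhaustively for all graphs with up to 4 nodes, plus seeded
random graphs with 5-8 nodes at a range of densities).

Two conventions deserve a note:

* Closeness is component-restricted (reachable count divided by summed
  distances), so disconnected networks still yield meaningful values.
* `densityFromCounts()` exposes both the unordered (2E / n(n-1)) and
  ordered (E / n(n-1)) readings of a printed edge count. Published
  module tables are sometimes only consistent with the ordered reading;
  the helper makes the check explicit instead of silently assuming one
  convention.

# Module detection

`fagecCluster()` implements fast agglomeration driven by edge
clustering coefficients, ECC(u, v) = (z + 1)/min(deg u - 1, deg v - 1)
with z the edge's triangle count. Edges are processed in non-increasing
ECC order (lexicographic tie-break); each edge merges the clusters of
its endpoints unless *both* clusters are already locked, where a
cluster locks once twice its internal edge count exceeds lambda times
its out-degree. Refusing only locked-locked merges is a deliberate
design decision: refusing any merge into a locked cluster lets
intermediate clusters lock themselves and block their own completion
(a complete graph K6 would stop at a 4-clique instead of agglomerating
fully), whereas two locked clusters are each self-contained modules
and gluing them together would undo the locking criterion's purpose.

`mclCluster()` implements Markov clustering: unit self-loops,
column-stochastic normalization, then alternating expansion (matrix
squaring) and inflation (entrywise power with renormalization) with
pruning below `tol`, reading clusters from the attractor structure.
Overlapping attractor claims resolve toward the larger cluster.

Both detectors recover planted-partition graphs (five blocks of 20,
p_in = 0.8, p_out = 0.02) exactly - Rand index 1.0 over ten seeds - in
the acceptance suite. `moduleSizeDistribution()` fits the truncated
power law log f(s) = log c - alpha log s - s/beta when at least three
distinct sizes are present, and reports `fit_available = FALSE`
otherwise rather than extrapolating.

# Promoter k-mer enrichment

The enrichment engine asks: do the promoters of a module share short
sequence elements beyond what a genomic background shows?

1. **Candidate generation** (`sharedKmerCandidates()`) aligns every
   promoter of the module against every other with an ungapped
   seed-and-extend aligner (word size 7, +1/-2 scoring, X-drop 10).
   Hits must reach 75% identity and a Karlin-Altschul E-value of at
   most 1e-4 over the search space (query length times total database
   length). All 6-mers of each passing hit's query-side span become
   candidates, minus any containing a homopolymer run of five or more.
2. **Scoring** (`bootstrapEnrichment()`) draws bootstrap replicates of
   the module size from the module promoters and from the background
   promoters, compares mean occurrences per promoter, and reports the
   fold ratio (cluster mean over background mean), a Welch t statistic
   on the replicate distributions, and the two-sided p-value. The
   bootstrap-t construction is anti-conservative (replicates are not
   independent samples); fold-ratio tiers (2x, 3x, 4x by default) are
   therefore the primary readout and the p-value is auxiliary.
3. **Evaluation** (`precisionEval()`) scores discovered 6-mers against
   a list of known elements; a k-mer is a true positive when it is a
   substring of a known element, or contains one, on either strand.

For the E-value the package solves the Karlin-Altschul equation
(1/4)e^lambda + (3/4)e^(-2 lambda) = 1 for +1/-2 scoring under uniform
base composition; the root has the closed form log((3 + sqrt 21)/2) =
1.3327, and K = 0.46 is used for the prefactor.

A structural consequence of alignment-driven candidate generation: a
hit needs a raw score around 20 to reach E <= 1e-4 at realistic search
spaces, so an isolated exact 6-mer can never produce a candidate.
Shared elements are discoverable when they are conserved blocks longer
than the seed word (the synthetic generator plants a 24-nt element by
default and recovery is scored on its constituent 6-mers). This
matches the biological target - clustered, repeated cis-regulatory
elements - rather than single degenerate motif instances, and it is a
known limitation for short isolated motifs.

# Synthetic data and nulls

`plantedExpressionTruth()` + `synthExpression()` plant co-expressed
gene blocks: each module follows a random ternary template across
conditions (frequencies 0.2/0.6/0.2 for -1/0/+1), each cell flips to a
different ternary value with probability `flip_prob` (default 0.1,
i.e. recoverable but noticeably corrupted; values >= 0.5 are rejected
because the planted structure is then unrecoverable by construction),
and background genes draw i.i.d. cells with frequencies 0.15/0.7/0.15
(sparse calls, as in real differential-expression compendia).

`randomizeExpression()` provides the matched nulls. The default
permutes each condition column independently: it preserves every
condition's up/down/no-change counts - the marginal a reviewer would
demand - while destroying all gene-gene dependence. Row, global and
i.i.d. modes are available for sensitivity checks.

`plantedMotifTruth()` + `synthPromoters()` generate promoter sets
(default 1000 bp, i.i.d. uniform ACGT background) with Poisson
per-promoter copy numbers of a planted element at non-overlapping
uniform positions, recording the true insertion sites.

# Reproducibility and numerical choices

Every stochastic operation takes an explicit seed and runs under
`withSeed()`, which restores the caller's RNG state. Identical
configuration and seed give byte-identical pipeline artefacts
(`runPipeline()` writes a JSON manifest recording all parameters).

Numerical conventions worth stating:

* Similarity matrices must be symmetric to within 1e-12; correlations
  are clamped to [-1, 1] against floating drift.
* mKNN tie detection uses an absolute tolerance of 1e-12 on
  correlation values.
* MCL prunes entries below 1e-6 and declares convergence below the
  same tolerance, warning (not failing) when the iteration cap is hit.
* Degree-<2 nodes have clustering coefficient and topological
  coefficient 0 by convention; isolated nodes have closeness 0 and
  undefined (NA) neighbourhood connectivity.

# Problem sizes

The packaged defaults (200-gene matrices, 100 conditions, four planted
modules of 25; 30-promoter modules against backgrounds of 100 or more)
are the package's own choices, sized so the full test battery,
including 50 motif-recovery replicates, runs in minutes on one CPU.
All operations scale to thousands of genes; all-pairs Kraskov MI is
the dominant cost (quadratic in genes, near-quadratic in conditions)
and is the reason the linear PCC path is the default pipeline method.

# Limitations

* The ternary encoding discards effect sizes; networks reflect call
  co-occurrence, not expression dynamics.
* The bootstrap enrichment p-value is anti-conservative by
  construction; use the fold tiers for decisions.
* The aligner is ungapped: indel-containing shared elements fragment
  into separate hits.
* Isolated short motifs (single 6-mers without a conserved flanking
  block) are invisible to alignment-driven candidate generation.
* The power-law fit is a log-log OLS on binned frequencies -- adequate
  for the qualitative scale-free check it supports, not a maximum
  likelihood tail estimate.
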