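---
title: "Comparing networks of different size and connectivity density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing networks of different size and connectivity density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcompare)
```

## The problem

Graph measures computed from brain connectivity data — the characteristic
path length $L$, the clustering coefficient $C$, the small-world index
$SW$, and most others — depend on the number of nodes $N$ and the average
degree $k$ of the network, in a way that is specific to the (unknown)
topology. Two recordings that differ only in overall connectivity strength
will, after thresholding, produce graphs with different $k$, and the
resulting differences in $L$ and $C$ are easily mistaken for genuine
topological effects. `netcompare` implements the construction schemes,
normalizations, simulation machinery and model-based comparison methods
needed to recognize, quantify and (partially) correct these size effects.

## From connectivity matrices to graphs

Empirical input is a symmetric matrix of connectivity values (coherence,
phase uniformity, correlation, fiber counts, ...) between all node pairs,
represented by `connectivity_matrix()`. Three binarization regimes are
provided by `binarize()`:

* **fixed threshold** — keep pairs with connectivity above $\tau$; between
  recordings, differences in overall connectivity then turn into
  differences in $k$;
* **fixed average degree** — per-network threshold chosen so that $k$ is
  constant; this forces noise edges into weakly connected networks and
  discards strong edges from densely connected ones;
* **fixed edge density** — keep a fixed fraction of all possible edges;
  for equal $N$ this coincides with fixed $k$ (property-tested).

Ties at the cut value are broken by descending connectivity, then
lexicographic node order, and counted in the report. `weighted_graph()`
skips binarization entirely; weighted measures use the conventions below.

The synthetic generator `synth_connectivity()` emulates such matrices: a
planted topology (typically Watts–Strogatz) contributes `base_strength`
on its edges, a `global_offset` shifts the overall connectivity level
between "conditions", and symmetric Gaussian noise is added before
clipping to $[0, 1]$. It reproduces the qualitative phenomenon that a
fixed threshold maps offset differences into degree differences, while a
fixed degree distorts the recovered structure. What it deliberately does
not emulate: volume conduction, spatially correlated noise, distance-
dependent connectivity fall-off, or subject-level variability — so tests
passing on synthetic matrices validate the algorithms, not any claim
about real sensor data.

## Measures and conventions

`path_length()` averages shortest-path hop counts over ordered reachable
pairs; for disconnected graphs the reachable-pair fraction is always
reported, and a strict mode errors instead. `clustering()` is the mean
local clustering coefficient with degree-$<2$ nodes contributing zero
(optionally excluded). These choices keep both measures defined for every
graph that has any edges; both are verified exactly against brute-force
BFS and triangle-enumeration oracles in the test suite.

Less common measures follow fixed conventions, documented rather than
asserted as anyone else's: synchronizability is the Laplacian eigenratio
$\lambda_{max}/\lambda_2$; central point dominance is Freeman's average
difference between the maximum normalized betweenness and each node's
value; hubs default to degree above mean $+ 2\,$SD of the degree
distribution (configurable, recorded in provenance). Weighted path length
uses inverse weights as distances and weighted clustering the
geometric-mean triangle convention with weights scaled by the maximum.

`analytic_measures()` transcribes the closed forms that make the
$N,k$-dependence explicit: $L_{lat} \approx N/2k$ and
$C_{lat} = 3(k-2)/(4(k-1))$ for ring lattices, $L_{ER} \approx \ln N/\ln
k$ and $C_{ER} = k/N$ for Erdős–Rényi graphs, the Newman–Moore–Watts
scaling function and the Barrat–Weigt factor $(1-p)^3$ for the
Watts–Strogatz model, and $\ln N/\ln\ln N$, $N^{-3/4}$ for
Barabási–Albert. Validity ranges ($N > 2k$ for lattice forms, $k > 1$
for ER) are enforced.

## Generators

`ring_lattice()`, `erdos_renyi()` (edge probability $k/(N-1)$),
`watts_strogatz()` and `barabasi_albert()` cover the canonical
topologies; `rewire_preserving_degrees()` provides Maslov–Sneppen
degree-preserving surrogates (double-edge swaps, default budget $10E$).

The Watts–Strogatz generator is written in the package rather than taken
from igraph because the analyses need per-edge bookkeeping: each edge
carries a `rewired` flag, so that a WS(100, 10, 0.1) draw can be checked
to carry $(1-p)Nk = 900$ local connection stubs in expectation, and edge
removal experiments can count how many local edges they destroyed. The
convention is the classic one: each lattice edge is independently
rewired with probability $p$ by redrawing its far endpoint uniformly
among targets that create no self-loop or duplicate. Note that at
$p = 1$ this is *not* exactly Erdős–Rényi — every node keeps its $k/2$
near endpoints, so the degree distribution is slightly narrower and the
ensemble clustering differs by a few percent; the tests assert 10%
relative agreement, not statistical identity.

For fixed-density sweeps where $k = \rho(N-1)$ is not an even integer,
`watts_strogatz_density()` starts from a nearest-integer lattice
(`whole nearest-neighbor rings first, leftover edges spread evenly
around the ring`) with exactly $\mathrm{round}(\rho N(N-1)/2)$ edges.
The same helper provides the lattice reference in range normalization.
`lattice_with_weights()` places an observed weight multiset randomly on
lattice slots and rewires with probability $p$ — the baseline model used
when estimating a rewiring probability for weighted empirical networks.

## Normalization and its bias

`surrogate_normalize()` divides $L$ or $C$ by its mean over 200 (the
package default, matching the repetition count used throughout) random
surrogates matched in $N$ and $E$ — or additionally in the whole degree
sequence. The central caveat, reproduced quantitatively by the acceptance
tests: for a ring lattice, raw $C = 3(k-2)/(4(k-1))$ is independent of
$N$, but $C/C_{rand}$ grows with $N$ because $C_{rand} \approx k/N$
shrinks. Normalization *introduces* a size dependence that the raw value
did not have, and the small-world index
$SW = (C/C_{rand})/(L/L_{rand})$ (`small_world_index()`) inherits it:
ensemble SW of WS($p=0.1$) networks roughly doubles from $N=100$ to
$N=200$ at fixed $k$. Degree-preserving and Erdős–Rényi references give
nearly identical results for WS networks (the path-length normalizations
agree within 2%).

`range_normalize()` instead expresses a measure as a position within the
range attainable between a matched lattice (deterministic reference) and
matched random graphs: $(x - \bar x_{rand})/(x_{lat} - \bar x_{rand})$.
A lattice maps to 1 by construction, a random graph to 0 in expectation,
and for small-world networks the cross-$N$ variability is orders of
magnitude below that of plain surrogate normalization — the package's
recommended default when a small-world-like topology is plausible.

## Estimating the size dependence, and model-based comparison

`estimate_k_dependence()` implements the edge-removal estimate: remove
edges uniformly at random down a grid of $k$ values and recompute $L$ and
$C$ (mean ± SD over repetitions). Because random removal destroys local
neighborhoods, the estimated $C(k)$ curve lies systematically below the
curve of networks generated directly at the lower $k$ — a bias toward
random structure that is much weaker for $L$, and that depends on the
source network's $k$. The acceptance suite shows a $> 50$-SE separation
at $k = 6$ from a WS(100, 10, 0.1) source.

`delta_distribution_test()` is the baseline-model comparison: simulate
pairs from a baseline model matched to the two observed $(N, k)$
configurations (2000 pairs by default), form the distribution of
simulated differences in a measure, and ask whether the observed
difference falls inside its central 95% interval. Outside means the
difference cannot be attributed to size effects alone — under the
baseline model. A percentile interval is used rather than a normal
approximation because simulated $\Delta$ distributions for small
networks are visibly skewed.

`estimate_p_rewire()` fits the rewiring probability of a WS baseline by
least squares on SW over a $p$-grid (default $0.01$–$1$ in steps of
$0.01$). Simulated SW at each grid point is an ensemble quantity: mean
$C$ and $L$ over draws, normalized by a shared matched random reference;
this keeps the cost linear in the grid size. Two numerical caveats are
built in: SW($p$) is non-monotone (it peaks at small $p$), so the
observed SW exceeding the whole simulated range only triggers the
boundary warning when the minimizer also sits at a grid end; and for
weighted inputs the simulator and reference carry the observed weight
multiset (`lattice_with_weights()` and random weight placement).

## Motif censuses and exponential random graph models

For directed graphs, `dyad_census_counts()` and `triad_census_counts()`
count the 3 dyad and 16 triad isomorphism classes (conventional
Davis–Leinhardt labels, `003` through `300`). The census classifies
every node triple against a canonical lookup table built at start-up by
brute-force canonicalization of all 64 labelled 3-node digraphs — the
same enumeration, re-implemented independently in R, is exposed as
`triad_taxonomy()` and confirms 16 classes of which 13 are weakly
connected. The census is cross-checked against igraph's implementation
in the tests. `motif_significance()` compares observed motif counts with
degree-matched Erdős–Rényi (default) or degree-preserving surrogates,
reporting z-scores and empirical two-sided p-values;
`functional_motifs()` expands a structural motif into the connected
sub-digraphs it contains.

`ergm_fit()` fits exponential random graph models
$P(Y = y) \propto \exp(\sum_\mu \theta_\mu g_\mu(y))$ with motif
statistics: arcs, mutual and asymmetric dyads, triads 201 and 021C,
2-in/out-stars, and directed 3-cycles (the star and cycle statistics are
fixed at these smallest orders). There is deliberately no implicit edges
term: coefficients are signed relative to the uniform random digraph
with edge probability ½, whose normalizer $n(0) = 2^{N(N-1)}$ anchors
the likelihood scale — hence the null deviance $2N(N-1)\ln 2$ (1206 for
$N = 30$, on $N(N-1) = 870$ degrees of freedom).

Estimation is maximum pseudo-likelihood (logistic regression of arc
indicators on change statistics, computed in compiled code) followed by
stochastic-approximation MCMC-MLE: at each of 10 iterations, networks
are sampled by single-arc-toggle Metropolis–Hastings at the current
$\theta$ and a damped Newton step moves $\theta$ toward the moment
condition $E_\theta[g] = g_{obs}$. The desk-scale default draws $10^4$
networks per iteration; `full_scale = TRUE` restores $10^5$. Numerical
safeguards worth knowing about:

* *thinning* between recorded samples defaults to half a dyad sweep,
  $N(N-1)/2$ proposals — slowly mixing triad statistics sampled more
  densely underestimate their variance, and with it the standard errors
  (the parameter-recovery acceptance test fails at 3-SE coverage with a
  tenth of this thinning);
* the thinning interval is odd, because a chain that accepts every
  proposal (as at $\theta = 0$) would otherwise lock the parity of the
  edge count between samples;
* standard errors come from the inverse covariance of the sampled
  statistics (estimated Fisher information); a ridge of $10^{-6}$ on the
  diagonal guards near-singular covariance;
* a fit whose final sampled statistics fail to bracket the observed
  values is flagged `degenerate`, with residual quantities withheld —
  the usual failure mode of over-rich motif models;
* observed statistics equal to zero (or a complete graph for the edges
  statistic) are rejected up front: the MLE would sit at infinity.

The log-likelihood — needed for residual deviance, AIC and Akaike
weights (`akaike_weights()`) — is estimated by path sampling along 10
bridges from $\theta = 0$ (where graphs are sampled directly and the
normalizer is analytic) to $\hat\theta$, with a delta-method Monte-Carlo
standard error. `ergm_exact_mle()` enumerates all $2^{N(N-1)}$ digraphs
for $N \le 4$ and provides the reference the MCMC path is tested
against (agreement within 0.05). `ergm_gof()` simulates networks at
$\hat\theta$ and reports 95% envelopes for the model statistics, the
full triad census and both degree distributions.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed, restores the caller's
RNG state, and re-runs bit-identically under the same seed. The
simulation studies in the test and acceptance suites use the package's
canonical conditions — 200 repetitions, WS rewiring probability 0.1,
$N$ up to 400 for small-world-index sweeps, 20 recovery trials at
$N = 30$ with 1500 sampled networks per fitting iteration — chosen so
the full suite completes in minutes on a single core while keeping all
Monte-Carlo checks at 3-SE resolution.

## Limitations

Graphs to be compared directly (distances, correlations, coincidence)
must have equal $N$; this is a property of the measures, not of the
implementation. Range normalization presupposes small-world-like
structure lying between lattice and random references. The edge-removal
estimate of $k$-dependence is demonstrably biased toward random
structure — that demonstration is its purpose. The ERGM sampler scales
as $O(N)$ per proposal for triad statistics and the census as $O(N^3)$;
both are comfortable for the $N \lesssim 200$ networks the package
targets, not for voxel-scale graphs. Exact structural distance is
limited to $N \le 8$ (factorial search); the annealed variant reports a
best-found value flagged approximate.
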