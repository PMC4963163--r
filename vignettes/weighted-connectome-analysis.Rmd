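---
title: "Weighted connectome analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted connectome analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wconn)
```

## The problem

Structural brain networks estimated from diffusion MRI tractography are
*dense*: with high seed densities, half of all region pairs can be joined
by at least one streamline. Classical binary graph analysis struggles
there, because a dense binary graph is close to complete — its clustering
is high simply because its density is high, and a degree-matched random
graph is just as clustered. The usual remedy, thresholding edges away
until the graph is sparse, is arbitrary: networks built at different
thresholds are not independent samples, and the conclusions change with
the cutoff.

`wconn` implements the complementary *weighted* framework: every edge
carries a dimensionless connection-strength weight computed from
streamline geometry, all metrics come in matched binary and weighted
forms, and topological statements (small-worldness in particular) are
made against null networks that preserve both the degree sequence and
the weight distribution. Under this framework the topological signal is
stable across thresholds, so thresholding becomes optional rather than
load-bearing.

## The edge weight

For the edge between regions $i$ and $j$, with retained streamline set
$R$,

$$w(e_{ij}) = \frac{V_{\mathrm{voxel}}}{P_{\mathrm{voxel}}}
  \cdot \frac{2}{A_i + A_j} \sum_{f \in R} \frac{1}{l(f)},$$

where $V_{\mathrm{voxel}}$ is the MR voxel volume (mm³),
$P_{\mathrm{voxel}}$ the number of tractography seeds per voxel, $A_i$
the surface area of region $i$ (mm²) and $l(f)$ the streamline length
(mm). Each streamline contributes $1/l$, so a coherent bundle spanning
$M$ voxels contributes on the order of its voxel count; dividing by the
seeds per voxel removes the seeding paradigm, and the area term removes
the node-size bias. Dimensionally, $\mathrm{mm}^3 \cdot \mathrm{mm}^{-2}
\cdot \mathrm{mm}^{-1}$ cancels: $w$ is dimensionless and exactly
invariant under a uniform spatial rescaling (lengths $\times s$, areas
$\times s^2$, volumes $\times s^3$) — a property the test suite asserts
to $10^{-12}$.

The implementation takes the inverse-length reading of the sum. The
alternative reading (multiplying by $l$ instead of dividing) is not
dimensionless and would grow with streamline length, contradicting both
the scale-invariance requirement and the interpretation of the sum as a
streamline-fiber count; we treat the inverse form as the intended one.

`characteristic_filter()` implements the membership rule for $R$: the
streamlines whose endpoints are exactly $\{i, j\}$, optionally excluding
streamlines seeded inside one of the two regions. Filtering of voxels
that do not belong to the white-matter path requires imaging context and
is deliberately left upstream: the package trusts the caller's
endpoint assignment.

## Thresholding on streamline counts

Edges are thresholded on the *number of streamlines*, never on the
weight: an edge survives `threshold_counts(x, T)` iff it is carried by
at least `T` streamlines (inclusive; `T = 0` is the identity). The
ceiling `max_possible_streamlines(M, spec)` of `M * P` streamlines for
an edge contained in `M` voxels anchors the scale: with 125 seeds per
voxel, a 2-voxel ("smallest plausible") edge can carry at most 250
streamlines, so a threshold of 25 keeps edges with at least 10% of that
ceiling. Thresholding is monotone (the edge set at a higher cutoff is a
subset of the edge set at a lower one) and commutes with binarization;
both properties are tested.

## Metrics

* **Degree / strength** — row sums of the binary and weighted adjacency
  matrices.
* **Geodesic paths** — binary: breadth-first hop counts. Weighted: the
  modified Dijkstra rule — among all paths joining a pair, restrict to
  those with the *fewest edges*, then take the *largest weight sum*.
  This keeps the weighted framework aligned with the binary one (the
  same paths are eligible) while using strength to rank them. It is
  computed by a layered max-plus dynamic program: the best weight sum
  over walks of exactly $h$ edges is propagated level by level, and the
  value is read off at $h$ equal to the pair's hop distance. A walk of
  exactly $h$ edges between nodes at hop distance $h$ can visit no
  vertex twice, so the program is exact; the suite verifies it against
  exhaustive path enumeration on 200 random graphs.
* **Clustering** — binary ($c_i = 2E_i / k_i(k_i{-}1)$); Onnela
  (geometric mean of the three scaled triangle weights, binary-degree
  normalization); Zhang–Horvath (triangle weight products over
  $(\sum_j \hat w_{ij})^2 - \sum_j \hat w_{ij}^2$, fully weighted).
  Weights are scaled by the network maximum (of the network *as
  currently thresholded*; each analysed network is self-contained), so
  all three coefficients live in $[0,1]$ and the weighted ones reduce
  exactly to the binary one on uniform weights. Nodes of degree
  $\le 1$ get 0 in all variants — the normalizations are undefined
  there and 0 is the standard convention.

Unreachable pairs are flagged `NA`, and `mean_geodesic()` refuses a
disconnected graph rather than silently averaging the finite entries;
`largest_component()` is the explicit opt-in for disconnected inputs.
The networks this package targets are dense (30–51% of all pairs
connected) and connected in practice.

## Null models and small-worldness

A null network preserves (1) the node count, (2) the exact degree
sequence — via Maslov–Sneppen double-edge swaps, 10 attempted swaps per
edge by default — and (3) the exact edge-weight multiset, by randomly
*permuting* the source's weights onto the rewired edges. Permutation
(sampling without replacement) is deliberate: it is the only scheme
that preserves the weight distribution exactly rather than in
expectation. Degree-sequence preservation is the strict reading of
"identical degree distribution"; swaps are the standard construction
that achieves it without multi-edges.

Small-worldness in mode $m \in \{\text{binary}, \text{onnela},
\text{zhang}\}$ compares the network to the null-ensemble means:

$$\gamma = c_g / c_N, \qquad \lambda = l_g / l_N, \qquad
  sw = \gamma / \lambda,$$

with clustering and path length always taken from the same framework
(binary clustering is never combined with weighted paths). Weighted
$\lambda$ uses the max-sum path lengths directly, without inversion,
even though a larger $d^w$ means a stronger path — the ratio is what
the framework compares. A small-world network shows $\gamma > 1$ with
$\lambda \approx 1$, hence $sw > 1$.

`n_replicates` defaults to 1 — one null per network, the historical
practice — but a single null is a recognized limitation, and 20 or more
replicates are recommended whenever the dispersion of $\gamma$,
$\lambda$, $sw$ matters; the `smallworld` object reports those standard
deviations.

## What the synthetic generators emulate

No deposited connectome accompanies this framework, so the package
ships generators that reproduce the *statistical conditions* of a dense
single-subject study, and all empirical claims in the test suite are
made on them.

**Dense connectome** (`generate_connectome`): 68 nodes, target density
0.51, uniform random topology. Edge weights are log-normal with
`meanlog = log(1e-3)`, `sdlog = 2.3`: the median sits at $10^{-3}$ and
the sample spans roughly $10^{-6}$–$10^{-1}$ over a dense network's
~1160 edges, the reported range for this edge weight. The heavy tail is
load-bearing: it makes the weakest ~40% of edges carry well under 1% of
the total weight, which is exactly why node strength is stable under
count thresholding while degree is not. Streamline counts follow
`count = max(1, round(1200 * w^0.3 * (1 + eps)))`, `eps ~ N(0, 0.15)`.
The exponent and prefactor were derived analytically from two anchors:
a count threshold near 10% of the maximum count should remove ~40% of
the edges (the reported density drop from ~51% to ~30% at the highest
threshold), and the count ceiling should sit near the $M \times P$
scale of the worked example. Counts are therefore strongly
rank-correlated with weights, so count-thresholding preferentially
removes weak edges, as in real tractography.

**Small-world reference** (`generate_smallworld_reference`):
Watts–Strogatz ring lattice ($n = 68$, $k = 34$ for ~50% density) with
rewiring that preserves the edge count exactly. The
`neighborhood-strong` weighting assigns strong weights (log-normal
around $10^{-2}$) to edges joining nodes within ring distance $k/2$ and
weak weights (around $10^{-4}$) to long-range edges — by endpoint
distance, not by lattice-vs-rewired identity, so the weight–topology
correlation survives rewiring. The default `p_rewire = 0.5` makes the
*binary* skeleton nearly random (binary $\gamma$ barely above 1, as
observed for unthresholded dense brain networks) while the weights
still concentrate in neighborhoods. This is the fixture behind the
headline property: at ~50% density the binary framework sees
$sw \approx 1$ while the Zhang-mode weighted framework sees $sw > 1$
in every seed tested.

**Session replicates** (`generate_session_replicates`): scan–rescan
variability is modelled as a per-edge multiplicative log-normal jitter
(CV 9.4%), a session-level global yield factor (CV 8%), and toggling of
weak edges so the per-session density fluctuates at the 3.6% level.
The global factor exists because with heavy-tailed weights a node's
strength is dominated by its largest edge, so independent per-edge
noise alone would produce node-strength CVs near 5%, well below the
~9.4% level seen across repeated sessions; a shared session factor is
also the physically natural model for global tractography-yield
variation. The defaults land the empirical density CV in 2–6% and the
mean node-strength CV in 6–13% across 10 sessions.

What the generators do **not** emulate: spatial embedding and
anatomy (no geometry beyond the ring fixture), tractography error
structure (false positives are not modelled as such), hemispheric or
modular organization unless requested (`n_communities`), and any
subject-level variability. Passing tests on these fixtures show that
the *framework* behaves as claimed under the stated statistical
conditions — not that any particular brain shows these values.

## Numerical and design choices

* Edge existence is strict positivity (`w > 0`); no epsilon.
* Asymmetric numeric input is symmetrized by averaging only when the
  asymmetry is at floating-point level (`1e-12` relative); anything
  larger is an error, because these networks are undirected by
  construction.
* Matrix I/O writes `%.17g`, so round trips are exact to the double
  representation; counts and labels round-trip exactly.
* The max-plus path program needs no tie-breaking: $d^w$ is a maximum
  of sums, so ties between path identities cannot change the value.
* Null-ensemble sub-seeds are derived as
  `(rng_seed + 11587 * replicate) mod (2^31 - 1)`, keeping every seed
  in integer range while decorrelating replicates deterministically.
* Graphs admitting no legal double-edge swap (complete graphs, a
  single triangle) are returned unchanged with a message; a complete
  uniform-weight graph is then exactly its own null and
  $\gamma = \lambda = sw = 1$, a fixed point the tests pin down.
* Density uses $N(N-1)/2$ as the possible-edge count (simple
  undirected graphs, diagonal excluded).

## Problem sizes used in the checks

The package's own validation runs at the study's native scale where
that is cheap (68 nodes, ~1160 edges; 20 null replicates; 20 seeds for
the distributional claims) and at reduced scale where an exhaustive
oracle is involved (path enumeration on graphs of up to 8 nodes, 200
seeds; triple-loop clustering oracles at 15 nodes). The full suite and
the acceptance script each complete in well under a minute on a single
CPU.

## Limitations

* The weighted path length is threshold-sensitive (removing a weak
  direct edge replaces it with a stronger two-hop path), unlike node
  strength and Zhang clustering; this is a property of the framework,
  reproduced here, not a bug.
* Onnela clustering normalizes by the binary degree, so it inherits
  some threshold sensitivity; Zhang clustering is the fully weighted
  variant.
* Only undirected, non-negative, simple networks are supported; no
  betweenness, modularity, rich-club or efficiency metrics — the
  framework here is clustering/path/small-worldness.
* The streamline-record interface assumes endpoint assignment has
  already been done by the tractography pipeline.
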