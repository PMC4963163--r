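# wconn — weighted connectome construction and small-world analysis

Structural brain networks built from diffusion-MRI tractography are
dense: with high seed densities, roughly half of all region pairs are
connected by at least one streamline. In a binary graph that density
conceals topology — a dense graph is clustered because it is dense, and
small-worldness cannot be detected without arbitrary sparsification
thresholds. `wconn` implements the complementary **weighted
connectivity framework** for users analysing dense connectomes:

* a **dimensionless, scale-invariant edge weight** computed from
  streamline geometry,

  w(e_ij) = (V_voxel / P_voxel) · (2 / (A_i + A_j)) · Σ_{f ∈ R} 1 / l(f),

  with V the voxel volume, P the seeds per voxel, A_i the node surface
  areas and l(f) the streamline lengths of the retained set R;
* **streamline-count thresholding** (edges with ≥ T streamlines
  survive; the weight value is never thresholded);
* matched **binary and weighted network metrics**: degree and strength,
  hop-count geodesics and the modified-Dijkstra weighted geodesic
  (among minimum-hop paths, the maximum weight sum), and binary /
  Onnela / Zhang–Horvath clustering coefficients;
* **dual-constrained null models** preserving the exact degree sequence
  (Maslov–Sneppen rewiring) and the exact edge-weight multiset (weight
  permutation);
* the **small-worldness statistic** γ = c_g/c_N, λ = l_g/l_N,
  sw = γ/λ, per framework, with null-ensemble dispersion;
* **synthetic generators** emulating dense single-subject study
  conditions (68 nodes, ~51% density, weights spanning ~4 orders of
  magnitude, counts rank-correlated with weights, repeated-session
  replicates), used by the whole test suite;
* standard-format I/O (CSV matrix, tab-separated edge list, GraphML)
  and a thin command-line interface.

## Worked example

```r
library(wconn)

# a dense synthetic connectome under the study conditions
cn <- generate_connectome(synth_config(rng_seed = 1))
cn
#> Weighted connectome: 68 nodes, 1162 edges (density 0.510)
#>   edge weights: 5.85e-07 .. 1.09 (median 0.000918)
#>   streamline counts: 15 .. 1302

# streamline-count thresholding controls density but barely moves strength
graph_density(threshold_counts(cn, 125))
#> [1] 0.2998244
100 * abs(1 - mean(node_strength(threshold_counts(cn, 125))) /
            mean(node_strength(cn)))
#> [1] 0.6264786        # percent; mean degree drops by 41% at the same cutoff

# small-worldness of a dense weighted small-world network vs its nulls
fix <- generate_smallworld_reference(n = 68, k = 34, p_rewire = 0.5,
                                     rng_seed = 6001)
cfg <- null_model_config(n_replicates = 20, rng_seed = 1)
small_worldness(fix, mode = "zhang", config = cfg)
#> Small-worldness (zhang mode, 20 null replicates)
#>   clustering:   c_g = 0.1229, c_N = 0.08524  ->  gamma  = 1.442
#>   path length:  l_g = 0.02146, l_N = 0.02209  ->  lambda = 0.971
#>   sw = gamma / lambda = 1.485
#>   null dispersion: sd(gamma) = 0.030, sd(lambda) = 0.005, sd(sw) = 0.033
small_worldness(fix, mode = "binary", config = cfg)$sw
#> [1] 1.019284
```

The contrast in the last two numbers is the point of the framework: at
~50% density the binary skeleton is nearly indistinguishable from its
degree-matched null (sw ≈ 1), while the weighted framework still
resolves the neighborhood-concentrated connection strengths (sw > 1).

The edge weight itself is available at the streamline level:

```r
spec <- parcellation_spec(voxel_volume_mm3 = 1, seeds_per_voxel = 125,
                          surface_areas_mm2 = c(a = 100, b = 100))
max_possible_streamlines(2, spec)      # 2-voxel edge ceiling: 250
st <- generate_streamline_fixture(
  data.frame(node_a = "a", node_b = "b", n_streams = 250, length_mm = 2),
  spec)
build_connectome(st, spec, c("a", "b"))$weights["a", "b"]
#> [1] 0.01
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "wconn.R", package = "wconn"))')" \
  simulate connectome --seed 7 --out conn.graphml
Rscript .../wconn.R smallworld --in conn.graphml --in-format graphml \
  --thresholds 0,25,50,125 --null-replicates 20 --seed 7 --out table.tsv
```

Subcommands: `convert`, `threshold`, `build`, `metrics`, `null`,
`smallworld`, `simulate`, `report` (the last writes the full
threshold-sweep report with a run manifest).

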