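# spotempo

Trajectory inference for spatial transcriptomics: pseudotime, lineage
paths and velocity fields that use **where** cells sit in the tissue as
well as **what** they express.

## Who this is for

Spatial transcriptomics assays (Visium-style spot arrays, imaging-based
single-cell platforms) measure an expression profile at each position of a
tissue section. When the section hosts a continuous process — development,
regeneration, tumour expansion — the analysis task is to order the
cells/spots along that process and render its local direction. Methods
built for dissociated single cells use only expression similarity and
produce noisy, spatially incoherent orderings; `spotempo` is for analysts
who want the tissue geometry in the model.

## The method

Given an expression matrix `X` (n cells × m genes) and coordinates
`s_i ∈ R²`:

1. **Spatial graph.** The alpha-complex 1-skeleton at scale δ (the radius-
   restricted Voronoi adjacency), built from the Delaunay triangulation
   with the Gabriel/circumradius filtration; δ defaults to the mean k-NN
   distance (k = 6).
2. **Joint embedding.** A masked two-layer MLP gives a feature embedding
   `Zf`; a two-layer variational GCN on the spatial graph gives `Zg`;
   `Z = [Zf ‖ Zg]`. Two-stage training (reconstruction + VGAE + mask-token
   losses, then a DEC clustering term), Adam, fixed seed.
3. **Density-adaptive fusion.** Per-cell Gaussian-kernel density ρ̂,
   min–max normalized, maps to a spatial weight
   `α_i = α_min + (1 − ρ_i)(α_max − α_min)` (defaults 0.2–0.8); cells at
   tissue edges, holes, or with unreliable connectivity get a fixed
   conservative weight. The transport cost is the row-indexed mixture
   `M_ij = α̃_i·d_s(i,j) + (1 − α̃_i)·d_g(i,j)` of max-normalized spatial
   and embedding distances.
4. **Optimal transport.** `P = argmin ⟨P, M⟩_F + γ Σ P log P` under uniform
   marginals (log-domain Sinkhorn, γ = 0.1), with the diagonal of `M` set
   to 10⁶ to forbid self-transitions.
5. **Trajectory readouts.** Pseudotime `τ` from accumulated transition
   probability out of a user-chosen start set (normalized ranks, oriented
   so τ≈0 is the initial state); least-action lineage paths on the
   `−log P` graph; per-cell velocities
   `v_i = (1/|N_i|) Σ γ_ij (s_j−s_i)/‖s_j−s_i‖` over spatial∪embedding
   neighbours, kernel-interpolated onto a grid and integrated into
   streamlines; spline-based pseudotime-dependent gene scores.
6. **Multi-section data** are embedded into one PCA+UMAP space, inferred
   per section, and the velocity fields pooled on a unified grid.

A seeded synthetic-trajectory simulator (branching topologies × spatial
patterns, ground-truth time/branch/direction) drives all benchmarks.

## Worked example

```r
library(spotempo)

sim <- simulate_trajectory(sim_config("bifurcating", "linear_map",
                                      n_cells = 300, seed = 42))
sim$dataset
#> spatial_dataset: 300 cells x 200 genes
#>   cell types: late_branch_1, late_branch_2, mid_trunk, mid_branch_1, origin, mid_branch_2

start <- select_start(sim$dataset, "by_type", target_type = "origin")
cfg <- run_config(seed = 42, encoder = encoder_config(epochs_pretrain = 100,
                                                      epochs_finetune = 100))
bundle <- run_pipeline(sim$dataset, start, cfg)
bundle
#> trajectory_bundle [full, seed 42, hash 1d5d441c]: 300 cells, tau in [0.00, 1.00]
bundle$tm
#> transition_matrix: 300 x 300, gamma = 0.1, 40 iterations, converged (violation 1.13e-10)

round(evaluate_pseudotime(bundle$pt$tau, sim$true_time), 3)
#> spearman  kendall
#>    0.974    0.869
```

The Spearman/Kendall pair compares inferred pseudotime with the
simulation's ground-truth time — 0.974 means the inferred ordering is
essentially the true developmental ordering. The bundle also carries the
transition plan (`bundle$tm`), per-cell velocities (`bundle$vf`), the grid
field and streamlines, and the density weights (`bundle$weights`).

```r
lap <- least_action_path(bundle$tm, source = start$indices[1],
                         sink = which.max(bundle$pt$tau), graph = bundle$graph)
length(lap$waypoints); round(lap$cost, 2)
#> [1] 7
#> [1] 15.35

tg <- trend_genes(bundle$dataset, bundle$pt)
head(tg$scores[order(-tg$scores$score), ], 3)
#>       gene     score rank
#> 34 prog_14 0.6430595    1
#> 32 prog_12 0.6217826    2
#> 37 prog_17 0.6168654    3
```

The least-action path traverses 7 waypoints from an origin cell to the
latest cell; the top trend genes are (correctly) the simulator's shared
developmental-program genes.

A command-line front end is installed with the package
(`system.file("cli/spotempo", package = "spotempo")`) with `run`,
`multirun`, `simulate` and `benchmark` subcommands.

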