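# vaxscape

Generative landscape-network models of spatial clustering in vaccine
hesitancy.

Vaccine-hesitant communities cluster geographically, and those contiguous
pockets of under-vaccination — not national averages — are what lets a
measles-class pathogen find room to spread. `vaxscape` is for modellers and
infectious-disease epidemiologists who want to ask *which social process
produces that clustering and what would break it up*. It implements, on
tunable Watts-Strogatz landscapes of communities:

* **Social selection** — communities with similar hesitancy-linked traits
  occupy adjacent positions. Homophily is measured by the mean edge-wise
  Mahalanobis form
  μ = |E|⁻¹ Σ₍ᵢⱼ₎∈E (Xᵢ−Xⱼ)ᵀ S⁻¹ (Xᵢ−Xⱼ),
  summarised as the selection level **β = 1 − μ/μ̃** against a
  random-placement baseline μ̃, and *installed* at a target β\* by a swap
  annealer that conserves the hesitancy distribution exactly.
* **Social influence** — bootstrap-percolation style diffusion: at each
  synchronous step a community whose neighbourhood exposure reaches a
  tolerance **α** raises its hesitancy η by δ = 0.01; a community crossing
  η ≥ 1 − ρ (ρ = 1 − 1/R₀ = 0.95 for measles) becomes *vulnerable*. Runs
  start at 10% vulnerable and stop at 25%.
* **Spatial clustering** — a categorical assortativity coefficient *r* of
  the vulnerable/protected partition over the spatial substrate (the
  unrewired ring), in a full-mixed-marginal variant and the standard
  (Newman, edge-end-accounting) variant, plus vulnerable-cluster size
  distributions and the maximum outbreak size.
* **Estimators** — α̂ (mean neighbourhood exposure of communities that
  increased), β̂ (selection level of observed traits on observed ties),
  node-subsampling bootstrap intervals, and forward validation by F-score.
* **Interventions** — trait-and-conformity targeting by the index
  ζᵢ = exp(Σᵤ z(Xᵤᵢ)) · (mean neighbour distance)⁻¹ with
  high-hesitancy and random comparators, and protective edge rerouting
  with probability ω, all scored as clustering relative to a no-action
  control.

Everything runs on synthetic county-like data generated by the package
itself; no external data are required.

## Worked example

```r
library(vaxscape)

# a 512-community landscape with 20% aspatial ties, 10% initially vulnerable
net <- ws_network(n = 512, k = 6, p = 0.2, seed = 1)
nodes <- traits_from_hesitancy(
  sample_hesitancy(512, calibrate_lambda(0.10), seed = 2)
)
net
#> <landscape_network> 512 nodes, 1536 edges (mean degree 6.00), p = 0.2, 1536 substrate edges

# install social selection at beta* = 0.4, then diffuse at alpha = 0.2
fit <- anneal_to_beta(net, nodes, beta_target = 0.4, seed = 3)
fit
#> <vh_anneal> beta = 0.3920 (target 0.400, tol 0.010), 264 swaps, converged
traj <- run_influence(net, fit$nodes, influence_params(alpha = 0.2))
glance(traj)
#> # A tibble: 1 × 6
#>   n_steps stop_reason      vulnerable_fraction     r n_clusters max_cluster
#>     <int> <chr>                          <dbl> <dbl>      <int>       <int>
#> 1       5 fraction_reached               0.275 0.530          22          17
```

Five synchronous steps take the landscape from 10% to 27.5% vulnerable
(the stop rule is the first crossing of 25%; the last wave overshoots).
The final spatial assortativity r = 0.53 says vulnerable communities are
strongly clumped on the geographic substrate — 22 clusters, the largest
spanning 17 communities, which is the largest contiguous pool an
introduced case could percolate through. `autoplot(traj)` draws the
trajectory, and `tidy(traj)` returns the per-step record.

Scoring an intervention against doing nothing:

```r
out <- evaluate_strategy("target_selection", reps = 20, seed = 4)
round(mean(out$relative_clustering), 3)
#> [1] 0.14
```

Protecting the 10% of communities with the highest trait-and-conformity
index ζ cuts spatial clustering to 14% of its no-action level in this
scenario (β\* = 0.4, p = 0.2).

Multi-condition sweeps go through `run_experiment()` /
`summarize_experiment()` (experiments: `selection_clustering`,
`influence_clustering`, `combined_clustering`, `strategy_comparison`,
`reroute_sweep`, `outbreak_size`), with a thin command-line wrapper in
`scripts/vaxscape-sim` for batch use.

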