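# succ

Quantitative toolkit for characterising **microbial community succession
under heavy-metal stress** — the analysis stack used in mine-tailings
primary-succession studies, where bare tailings are colonised by biological
soil crusts while metal contamination filters the bacterial and fungal
communities that can establish.

It is written for microbial ecologists who have (a) a sample × ASV count
table, (b) a rooted phylogeny over those ASVs, and (c) per-sample
physicochemical measurements (nutrients and metal concentrations), and who
want the full chain from pollution characterisation to assembly-process
inference in one reproducible, seeded pipeline.

## What it computes

* **Pollution indices** — geo-accumulation index
  `Igeo = log2(Cn / 1.5 Bn)`, single pollution index `PI = Ci / Si`, and the
  per-sample Nemerow composite `NIPI = sqrt((PI_ave² + PI_max²)/2)`, with
  Welch *t* group contrasts and Benjamini–Hochberg adjustment.
* **Diversity & permutation statistics** — richness, bias-corrected Chao1,
  Shannon, Pielou; Bray–Curtis distances; Mantel and partial Mantel tests
  (999 permutations, one-sided); one-way PERMANOVA.
* **Co-occurrence networks** — per-group Pearson networks on
  log-transformed abundances of the top-N ASVs (edges at |ρ| > 0.3,
  p < 0.05), the topological metric suite (connectance, average degree,
  global/average clustering, average neighborhood connectivity, degree and
  eigenvector centralization), seeded Louvain modules,
  module–environment correlations, per-sample **cohesion**, and a composite
  **complexity** score min-max standardised across networks.
* **Community assembly** — abundance-weighted βMNTD with a tip-shuffling
  null (βNTI), the Bray–Curtis Raup–Crick index from a probabilistic
  occupancy/abundance null, and the five-process classification
  (heterogeneous/homogeneous selection, dispersal limitation, homogenizing
  dispersal, undominated) with per-group process fractions:
  |βNTI| ≥ 2 → selection (sign gives the subtype); otherwise
  RC > 0.95 → dispersal limitation, RC < −0.95 → homogenizing dispersal,
  |RC| < 0.95 → undominated.
* **Synthetic communities with known truth** — Yule phylogenies, Brownian
  niche traits, log-series metacommunities, and assembly under
  environmental-filtering / neutral / dispersal-limited regimes, plus
  group-structured metal concentrations and gradient-linked nutrient
  variables, so every stage can be validated against ground truth.

## Worked example

```r
library(succ)

# a desk-scale two-mine study: 2 pollution groups x 2 stages x 3 replicates
sim <- simulate_study(n_taxa = 120, depth = 5000, seed = 42)

idx <- pollution_indices(sim$metals, sim$backgrounds, sim$screening)
compare_groups(data.frame(NIPI = idx$per_sample$nipi), sim$truth$group)
#>   variable statistic            p        p_adj
#> 1     NIPI  7.952449 0.0003086181 0.0003086181
```

Group H (copper-mine-like multipliers) reaches NIPI 8.31 ± 1.75 against
2.49 ± 0.41 in group L — a strong, significant contamination contrast driven
by the Cu single-pollution index, exactly the structure such indices are
meant to expose.

```r
head(alpha_diversity(sim$table), 3)
#>   sample richness    chao1  shannon    pielou
#> 1    HT1       85 100.1111 3.150125 0.7090642
#> 2    HT2       87 117.0000 3.137808 0.7026138
#> 3    HT3       93 103.2000 3.171386 0.6996837

res <- assembly_analysis(sim$table, sim$tree, n_null = 199, seed = 1)
subset(res$fractions, fraction > 0)
#>   group                 process fraction n_pairs n_na
#> 1     H heterogeneous_selection      0.2      15    0
#> 4     H  homogenizing_dispersal      0.8      15    0
#> 9     L  homogenizing_dispersal      1.0      15    0
```

Per-pair βNTI/RC values classify every within-group sample pair; the
neutral group L is entirely stochastic (|βNTI| < 2 with RC < −0.95: samples
are *more* similar than the occupancy null expects, i.e. homogenizing
dispersal), while the filtering group H shows a deterministic component.

```r
h_samples <- sim$truth$sample[sim$truth$group == "H"]
net <- build_network(subset_table(sim$table, samples = h_samples,
                                  drop_empty_taxa = TRUE))
net
#> cooc_network: 107 nodes, 293 edges (145 positive, 148 negative)
round(topology_metrics(net), 3)
#>   n_nodes n_edges connectance avg_degree   gcc   acc    an    cd    ec
#> 1     107     293       0.052      5.477 0.473 0.481 6.137 0.063 0.437
```

The whole chain — pollution, diversity, Mantel screens, per-group networks
with modules/cohesion/complexity, assembly fractions — runs end to end from
files with `run_pipeline(run_config(...))`, writing one TSV per result plus
a JSON record of every threshold and the seed; a given seed reproduces the
bundle byte for byte.  A thin command-line wrapper with the same stages
lives at `inst/cli/succ.R` (subcommands `run`, `simulate`, `pollution`,
`diversity`, `network`, `assembly`).

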