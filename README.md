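# netdegrade

Data-handling error models for network diffusion simulations.

Computational models of spreading processes — epidemics, rumours, cascading
failures — run on networks built from data, and the cleaning/integration
steps between data collection and model input can silently change that
network. `netdegrade` is a laboratory for quantifying the downstream effect:
it generates or loads a graph, degrades it with an explicit data-handling
error model, runs a diffusion model on the intact and degraded versions, and
compares the outputs. It is aimed at modellers and data engineers who want
to know *how wrong their model output can be* given plausible handling
errors, before trusting conclusions drawn near a critical regime.

## What is inside

**Graphs** — Erdős–Rényi G(n, M) (`generate_er`), Watts–Strogatz ring
rewiring (`generate_ws`), Barabási–Albert preferential attachment
(`generate_ba`), plus a SNAP-dialect edge-list loader/writer
(`load_edge_list`, `write_edge_list`) that collapses duplicates and
self-loops and keeps the original-id map.

**Handling error models** —

* batched random node/edge removal (`remove_nodes_random`,
  `remove_edges_random`, `batch_schedule`);
* entity-resolution-style aggregation: skew-normal attributes
  (`sample_skew_normal`, shape α = 4), equal-width binning (`bin_values`,
  50 bins), and merging of same-bin node pairs whose shared-neighbour
  proportion

  max(|S|/|N(i)\\{j}|, |S|/|N(j)\\{i}|),  S = common neighbours,

  strictly exceeds a threshold p (`systematic_aggregation`), with a
  merge-count-matched random baseline (`random_aggregation`).

**Diffusion** — a discrete-time SIR engine (per-contact Bernoulli(β)
transmission, Bernoulli(γ) recovery, snapshot update order) and a
synchronous Threshold cascade (activate when strictly more than φ of
neighbours are infected), both in compiled code, with summary metrics
(attack rate, additional infected beyond the seeds, peak, time to peak,
time to stability).

**Experiments** — the three replicated designs (removal on synthetic
graphs, aggregation on synthetic graphs, removal on a loaded real-world
graph), fully derived seeding so every table row is independently
re-runnable, sigmoid transition-curve fitting (`fit_sigmoid`), and β
calibration to a target attack rate on a fixed grid (`calibrate_beta`).

**CLI** — `generate`, `degrade`, `diffuse`, `experiment`, `fixture`
subcommands (`run_cli()`, launcher in `inst/exec/netdegrade`), with the
full simulation parameter grid shipped as presets
(`list_presets()`; e.g. `sir-aggregation-ws`, `threshold-removal-er`).

## Worked example

```r
library(netdegrade)

g <- generate_ws(500, 50, 0.1, seed = 1)
g
#> <netgraph> 500 nodes, 12500 edges
normalized_average_degree(g)
#> 0.100200   # the average node has ~10% of its possible partners

lv <- aggregation_levels(g, aggregation_config(alpha = 4, n_bins = 25,
                                               shared_threshold = 0.8),
                         seed = 2)
lv$report
#> <aggregation_report> 62 merges; degraded graph: 438 nodes, 10097 edges

params <- sir_params(beta = 0.005, gamma = 0.2, init_frac = 0.05)
for (nm in c("none", "shared_neighbor", "random")) {
  attack <- mean(sapply(1:10, function(i)
    summarize_diffusion(run_sir(lv[[nm]], params, seed = i),
                        "total_infected_frac")))
  cat(sprintf("%-16s mean attack rate over 10 runs: %.3f\n", nm, attack))
}
#> none             mean attack rate over 10 runs: 0.338
#> shared_neighbor  mean attack rate over 10 runs: 0.308
#> random           mean attack rate over 10 runs: 0.503
```

Reading: merging look-alike nodes (62 merges, ~12% of the graph) *lowers*
the predicted epidemic size a little, while the same number of random
merges *raises* it by half — the two aggregation policies, identical by
merge count, push the model in opposite directions. At the full study scale
(2,500 nodes, 20 graphs × 10 runs) the same reversal appears between the
Threshold and SIR models as well.

## Command line

```sh
Rscript inst/exec/netdegrade generate --topology ws --n 2500 \
    --ws-k 250 --rewire 0.1 --seed 7 --out ws.txt
Rscript inst/exec/netdegrade experiment --preset sir-aggregation-ws \
    --seed 1 --scale 0.25 --out-dir results/
```

Every experiment writes a tidy CSV (`graph, level, replicate, metric,
value`) and a JSON run manifest (config snapshot, base seed, seed
derivation rule) sufficient to reproduce any row. Exit codes: 0 success,
2 configuration error, 3 runtime failure.

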