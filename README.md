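# rcdiff

Simulation and seed-selection toolkit for the diffusion of **multiple
costly behaviors** through a social network of **resource-constrained**
individuals — the setting of public-health campaigns and viral
marketing, where a participant may want to adopt a behavior her friends
practice but lacks the time or money to do so.

## The model

On an undirected graph `G = (V, E)`, each behavior `i` has a cost
`c_i ∈ [0,1]` and utility `u_i ∈ [0,1]`; each node `v` holds a known
resource `r(v) ∈ [0,1]` and a private threshold `θ_i(v) ~ U(0,1)` per
behavior. Neighbors exert influence `1/|N(v)|`, so the social signal
`l_i(v)` is the adopting fraction of the neighborhood. In synchronous
epochs, behavior `j` becomes a *candidate* at `v` when
`l_j(v) ≥ θ_j(v)` and `v` can afford it, and `v` adopts the candidate
subset `B` maximizing the payoff

```
Σ_{i∈B} p_i(v),   p_i(v) = w·u_i + (1−w)·l_i(v),   s.t.  Σ_{i∈B} c_i ≤ r(v)
```

— a per-node knapsack generalization of the Linear Threshold model (to
which it reduces when `k = 1, c_1 = 1, r ≡ 1`). Sticky (progressive) and
re-evaluation dynamics are both provided. On top of the dynamics the
package implements:

* three synthetic topology generators (preferential attachment,
  small world, spatially clustered) and a SNAP-dialect edge-list
  reader/writer;
* Monte-Carlo estimators of expected participation, adoption and
  resource utilization under threshold-average and network-average
  randomness regimes, with a compiled (Rcpp) diffusion engine;
* the equivalent live-edge sampling process, used to validate the
  dynamics and to verify the submodularity that gives the greedy
  algorithm its `1 − 1/e` guarantee;
* closed-form utilization analytics (full utilization points, the
  staircase-integral bound, optimal point spacing);
* nine seed-selection algorithms — simulation-based submodular greedy,
  exact expected-immediate-adoption (EIA), constrained social influence
  weight (CIW, ranked and max-margin), degree-based heuristics and a
  random baseline — in single/multiple-behavior and
  top-up/no-top-up variants;
* five strategies for distributing behaviors over the seed set, and an
  experiment harness (`run_table()`) reproducing the reference
  simulation tables at any scale.

## Worked example

Seed a 500-node preferential-attachment network with 51 early adopters
chosen by the CIW max-margin heuristic (17 per behavior, top-up
variant), then estimate the equilibrium metrics over 500 threshold
resamples:

```r
library(rcdiff)
b <- behavior_set(c(0.2, 0.5, 0.7))        # utility = cost
max_utilization(utilization_points(b))     # analytic ceiling: 0.78

g <- gen_preferential_attachment(500, rng_seed = 1)
set.seed(2); r <- runif(500)               # resources are public
seeds <- select_ciw_max_margin(g, r, b,
           distribute_behaviors("uniform", 51, b), rng_seed = 3)
seeds
#> Seed assignment (S-T): 51 seed slot(s) over 3 behavior(s)
#>   behavior 1: 17 seed(s)
#>   behavior 2: 17 seed(s)
#>   behavior 3: 17 seed(s)
#>   27 seed(s) topped up by 7.080 in total

estimate_metrics(g, b, function(graph, rr) seeds, w = 0.5,
                 runs = 500, rng_seed = 4, r = r)
#> Monte-Carlo estimate (threshold_avg, 500 runs, mode reevaluate, w = 0.50):
#>   participation 226.6940 (se 0.3075)
#>   adoption      229.5560 (se 0.3607)
#>   utilization   0.3936 (se 0.0006)
```

About 227 of 500 nodes end up practicing at least one behavior on this
instance, spending ~39% of the network's total resource — against an
analytic ceiling of 78% for these costs, and ~12–15% for randomly
chosen seeds. `run_table(3, ...)` runs the full heuristic × topology
grid and returns one provenance-carrying row per cell; a thin CLI over
the same functions ships in `inst/cli/rcdiff`.

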