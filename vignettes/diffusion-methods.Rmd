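---
title: "Resource-constrained multiple-behavior diffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-constrained multiple-behavior diffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcdiff)
```

## The adoption model

`rcdiff` simulates the spread of $k$ costly behaviors over an undirected
social graph $G = (V, E)$ of resource-limited individuals. Behavior $i$
carries a cost $c_i \in [0,1]$ and an intrinsic utility $u_i \in [0,1]$,
both intrinsic to the behavior (identical for all individuals; this is a
deliberate simplification of the model). Each node $v$ holds

* a fixed resource $r(v) \in [0,1]$, treated as *known* — the scenario is
  a health-behavior or viral-marketing campaign in which participants
  declare the time or money they can commit;
* a private threshold $\theta_i(v) \sim U(0,1)$ per behavior, *unknown*
  to any seeding algorithm.

Every neighbor exerts the same influence weight $1/|N(v)|$ on $v$, so a
node's incoming weights always sum to one. The *social signal*
$l_i(v)$ is the fraction of $v$'s neighborhood that has adopted $i$.
Time advances in synchronous epochs. A behavior $j$ becomes a
*candidate* at $v$ once $l_j(v) \ge \theta_j(v)$ and $v$ can afford it;
the node then adopts the subset $B$ of its candidates maximizing the
total payoff $\sum_{i \in B} p_i(v)$ subject to
$\sum_{i \in B} c_i \le r(v)$, where

$$p_i(v) = w\,u_i + (1 - w)\,l_i(v).$$

This per-node knapsack is solved exactly by enumeration ($k$ is small);
payoff ties break toward the cheaper subset, then the lexicographically
smallest index set, so trajectories are fully reproducible. With $k = 1$,
$c_1 = 1$ and $r \equiv 1$ the model collapses to the classic Linear
Threshold model, a reduction the test suite verifies against an
independent LT implementation.

Two update dynamics are provided by `run_diffusion()`:

* **sticky** (progressive): adopted behaviors are never dropped, new
  adoptions are paid from the residual $r(v) - s(v)$, and the process
  terminates at the first unchanged epoch (guaranteed within
  $|V| \cdot k$ epochs). This is the variant for which the live-edge
  equivalence and the submodularity of expected participation hold,
  underpinning the greedy guarantee.
* **reevaluate**: every epoch each node re-optimizes its whole adopted
  set against its full budget. Already-adopted behaviors stay eligible
  without re-passing their threshold test (a node never "forgets" that a
  behavior crossed its threshold), seed-assigned behaviors are pinned,
  and dropping happens only through knapsack displacement. Because
  payoffs move with the signals, limit cycles are possible; the engine
  stops at a state fixed point or at `max_epochs` (default 1000) with
  `converged = FALSE`, which in practice affects a minority of runs and
  contributes only oscillation-phase noise to the metrics.

The source for which dynamics the reference tables used is not explicit;
the experiment harness defaults to re-evaluation (the main text
describes nodes re-evaluating all behaviors, including adopted ones,
each epoch) and records the mode in every output row. Empirically the
two modes give statistically indistinguishable table values under the
study conditions.

### The payoff weight `w`

The blend between intent and social signal is governed by $w$, which the
reference experiments never state. The package default is $w = 0.5$
(equal weight), it must be supplied explicitly anywhere results are
recorded, and every result row carries it. Note that *participation* is
insensitive to $w$ — candidacy is threshold-driven and any non-empty
candidate set yields a non-empty adoption — while utilization and the
adoption mix respond to it.

## Synthetic topologies

Three generators cover the qualitative regimes of real social networks;
all produce simple undirected graphs with deterministic vertex order.

* `gen_preferential_attachment(n)`: one node arrives at a time and links
  to an existing node with probability proportional to in-degree
  (links received) plus one — cumulative advantage. We read the source
  description literally: attachment follows the *in-degree*
  distribution, which for a growing tree equals the classic
  Barabási–Albert degree rule; smoothing by +1 makes the first
  attachment well defined. The heavier hub tail this produces (relative
  to an undirected degree+1 rule) is what reproduces the reference
  hub-seeding results.
* `gen_small_world(n, lattice_k = 2, p_rewire = 0.2)`: ring lattice plus
  independent rewiring; the reference configuration connects each node
  to its two ring neighbors, i.e. the lattice is a cycle. `lattice_k` is
  exposed because "connected to two adjacent nodes" could also be read
  as two per side.
* `gen_spatially_clustered(n, avg_degree = 10)`: uniform placement in
  the unit square, closest pairs linked until the mean degree reaches
  the target. The upstream description names only the summary statistic
  (mean degree 10), so this generator is an approximation that matches
  the stated statistic and exhibits the intended high clustering; it is
  documented as such.

These generators emulate degree heterogeneity, short paths and spatial
clustering, but none of them reproduces community structure, degree
assortativity or the fat-tailed *edge* multiplicities of real contact
networks. Passing tests therefore demonstrate correctness of the
machinery and reproduction of the reference simulation regime, not
predictions for any particular real network. Real edge lists (SNAP
dialect) are read with `read_edge_list()`.

## Metrics and Monte-Carlo regimes

Three metrics summarize a run: *participation* (nodes with at least one
behavior), *adoption* (behavior count summed over nodes) and *resource
utilization* $\sum_v s(v) / \sum_v r(v)$, with topped-up resources in
the denominator. `estimate_metrics()` averages them over

* **threshold average**: one topology, one resource draw and one seed
  selection held fixed; thresholds resampled each run. Resources sit on
  the "known" side of the model, so they belong to the fixed instance;
  consequently a threshold-average estimate carries an
  instance-to-instance spread (typically $\pm 0.01$–$0.015$ utilization
  at $n = 500$) that does not shrink with more runs — comparisons should
  average over several topology draws, as the acceptance suite does.
* **network average**: thresholds fixed by node index; topology,
  resources and seed selection redrawn each run. Requires a generator
  closure rather than a fixed graph.

The two regimes estimate the same expectation once topology draws are
averaged, and the suite checks their agreement empirically.

`max_possible_utilization()` implements the utilization ceiling
procedure: every node starts with its intrinsic-utility knapsack
optimum (equivalently the payoff optimum with no one else active), then
re-evaluation dynamics run to equilibrium during which nodes realign
with their neighbors — initial behaviors are deliberately *not* pinned,
since realignment is the phenomenon being measured. Before diffusion the
expected utilization equals the closed-form bound below; alignment pulls
it a few points under.

## Closed-form utilization analytics

With resources uniform on $(0,1)$ and free choice over behaviors, an
individual can spend at most the largest achievable subset-sum of costs
below its resource. The sorted distinct subset-sums
$\mu_1 < \dots < \mu_n \le 1$ are the *full utilization points*
(`utilization_points()`; float-equal sums are merged at $10^{-12}$), and
the maximum expected utilization is

$$U = 2\left(\mu_1\mu_2 + \dots + \mu_{n-1}\mu_n + \mu_n\right)
      - 2\left(\mu_1^2 + \dots + \mu_n^2\right),$$

the staircase integral normalized by $E[r] = 1/2$. For the study costs
$(0.2, 0.5, 0.7)$ the points are $\{0.2, 0.5, 0.7, 0.9\}$ and
$U = 0.78$. Stationarity gives the optimal spacing $\mu_i = i/(n+1)$
with value $n/(n+1)$ (`optimal_points()`); splitting the cheapest
behavior in half lifts $n$ points to $2n + 1$ and the relative
utilization by $1/(2n)$.

## The live-edge process

`sample_live_edges()` draws, per node, one incoming edge per behavior
the node could afford on its own ($\kappa(v)$ slots, computed from the
*original* resource, uniform over neighbors, with replacement);
`run_live_edge_process()` then runs sticky epochs in which behavior $j$
is considered only when the slot-$j$ neighbor adopted $j$. Payoffs use
the full-neighborhood signal (matching the base model; the source leaves
this open and the choice only affects knapsack tie composition, not
candidacy). The process is the package's independent validation device:
its per-node activation distribution matches the sticky model within
Monte-Carlo error, and on a fixed edge sample the participation
$\sigma'_X(S)$ is monotone and submodular in the seed set — both checked
exhaustively on small fixtures — which yields the $1 - 1/e$ guarantee
for the greedy algorithm.

## Seed selection

All selectors consume a per-behavior budget (`distribute_behaviors()`
apportions a total budget by largest remainder, remainder ties to the
lower index) and produce a `seed_assignment`. Variants: single (`S`) vs
multiple (`M`) behaviors per seed, crossed with top-up (`T`: a seed
short of resource has $r(v)$ raised to *exactly* the assigned cost —
additive top-ups would contradict the set-to-cost semantics — and the
raised resource enters the utilization denominator) vs no-top-up (`NT`:
only affordable nodes are eligible). Argmax ties everywhere are broken
uniformly at random from the caller's RNG stream, so selections are
reproducible under a seed.

In rough order of cost:

1. **random** — uniform seeds, the baseline.
2. **naive degree** (`random_nt`, `random_t`, `knapsack` tie rules) —
   scan by degree; the no-top-up rule consumes unaffordable nodes from
   the ranking without assigning them.
3. **degree + resource** — rank by $d_i(v)$, the count of neighbors able
   to afford behavior $i$; collisions between behaviors are resolved at
   random and shorted behaviors refill from the next rank.
4. **CIW rank / CIW max-margin** — the Constrained Social Influence
   Weight $e_i(v) = 1 + \sum_{u \in N(v),\, r(u) \ge c_i} 1/|N(u)|$; the
   max-margin variant re-picks greedily, decrementing each neighbor's
   score by $1/|N(u)|$ after a pick (the decrement is unconditional,
   following the source pseudocode).
5. **EIA** — incremental greedy on the exact expected one-step adoption
   $IA_i(S)$: with uniform thresholds behavior $j$ is a candidate
   independently with probability $l_j(v)$, so the one-step adoption
   probability of each node is an exact $2^k$-term enumeration
   (`compute_ia()`). Marginal gains are evaluated only over the
   candidate's neighborhood, which is what makes the heuristic cheap.
   Cross-behavior comparison uses the marginal gain relative to the
   current seed set (reading "maximizes the marginal increase" of the
   source literally).
6. **greedy (simulation)** — the submodular hill-climb: each candidate
   is scored by Monte-Carlo sticky participation (`spread_runs` fresh
   threshold draws; default 1000, reduced in small-instance experiments)
   and the best (behavior, node) pair is committed. `spread_fn` lets
   tests substitute exact enumeration for the estimator.

Behavior distribution strategies over the seed set (`lowest_only`,
`inverse_cost`, `uniform`, `proportional_cost`, `highest_only`) trade
participation against utilization: cheap behaviors spread widest,
expensive ones spend most.

## Numerical choices and degenerate inputs

* Floating-point comparisons use a $10^{-12}$ slack; the threshold test
  is $l \ge \theta$ (the boundary has measure zero under continuous
  thresholds).
* Isolated nodes have zero signal and can only ever activate as seeds.
* Knapsack tie-breaks (cost, then lexicographic) are identical in the R
  reference implementation and the compiled engine.
* The re-evaluation epoch cap (default 1000) converts potential limit
  cycles into flagged, truncated runs rather than errors; metric
  estimates report the fraction of truncated runs.
* Seed derivation in the experiment harness keeps all derived seeds
  below $2^{31}$.

## Scale of the shipped experiments

The package defaults mirror the reference conditions: $n = 500$
synthetic networks (100 for the greedy comparison), costs
$(0.2, 0.5, 0.7)$ with utility equal to cost, seed fraction
$\alpha = 0.1$ giving budgets of 51 (and 9 on the small instances), and
5000 Monte-Carlo runs per configuration in `run_table()`. The test and
acceptance suites run the same pipelines at reduced scale — typically
3–12 topology draws of 110–170 threshold resamples each, chosen so that
Monte-Carlo standard errors are comfortably below the tolerances being
checked — and compare stochastic table values within three standard
errors over topology draws, since the reference values are themselves
single-topology estimates with an instance spread of roughly
$\pm 0.015$ utilization.

## Known limitations

* Exact expected metrics are #P-hard; everything beyond tiny fixtures is
  Monte-Carlo.
* The closed-form utilization results assume $r \sim U(0,1)$;
  non-uniform resource distributions are out of scope.
* Utilities are homogeneous across individuals; behavioral inertia,
  noisy signals and epidemic-style relapse are not modeled.
* The spatially clustered generator matches the stated mean degree and
  qualitative clustering, not a specific published algorithm.
* The greedy guarantee covers sticky total participation only; for
  utilization or adoption objectives the greedy is a heuristic.
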