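#' Seed budget from a population fraction
#'
#' Converts a target early-adopter fraction `alpha` into a whole seed
#' budget divisible by the number of behaviors: the smallest multiple of
#' `k` not below `round(alpha * n)` (so `n = 500, alpha = 0.1, k = 3`
#' gives 51).
#'
#' @param alpha early-adopter fraction in `(0, 1]`.
#' @param n number of nodes.
#' @param k number of behaviors.
#' @return total seed budget (integer).
#' @export
seed_budget <- function(alpha, n, k = 3L) {
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must lie in (0, 1]")
  b <- as.integer(ceiling(round(alpha * n) / k) * k)
  if (b < 1L) stop_invalid("alpha * n rounds to an empty seed budget")
  b
}

#' Construct a seed-selection strategy
#'
#' Packages a heuristic, a budget and its distribution over behaviors
#' into a closure `function(graph, r) -> seed_assignment`, the interface
#' consumed by [estimate_metrics()] and [run_table()].
#'
#' @param heuristic one of `"random"`, `"degree_nt"`, `"degree_t"`,
#'   `"degree_knap"`, `"degree_resource"`, `"ciw_rank"`, `"ciw_margin"`,
#'   `"eia"`, `"greedy"`.
#' @param behaviors a [behavior_set()].
#' @param budget total seed budget, or a per-behavior `seed_budget`
#'   vector.
#' @param distribution behavior distribution strategy, see
#'   [distribute_behaviors()] (ignored when `budget` is already a
#'   vector).
#' @param variant seed variant (the naive-degree rules imply their own).
#' @param w payoff weight (used by `"eia"` and `"greedy"`).
#' @param spread_runs simulation runs per candidate for `"greedy"`.
#' @return a seeder closure drawing any internal randomness from the
#'   caller's RNG stream.
#' @export
make_seeder <- function(heuristic = c("random", "degree_nt", "degree_t",
                                      "degree_knap", "degree_resource",
                                      "ciw_rank", "ciw_margin", "eia",
                                      "greedy"),
                        behaviors, budget, distribution = "uniform",
                        variant = "S-T", w = 0.5, spread_runs = 1000L) {
  heuristic <- match.arg(heuristic)
  force(behaviors); force(budget); force(variant); force(w)
  force(spread_runs); force(distribution)
  function(graph, r) {
    bvec <- if (inherits(budget, "seed_budget")) budget else
      distribute_behaviors(distribution, budget, behaviors)
    switch(heuristic,
      random = select_random(graph, r, bvec, behaviors, variant),
      degree_nt = select_naive_degree(graph, r, behaviors, bvec,
                                      "random_nt"),
      degree_t = select_naive_degree(graph, r, behaviors, bvec,
                                     "random_t"),
      degree_knap = select_naive_degree(graph, r, behaviors, bvec,
                                        "knapsack"),
      degree_resource = select_degree_resource(graph, r, behaviors, bvec,
                                               variant),
      ciw_rank = select_ciw_ranked(graph, r, behaviors, bvec, variant),
      ciw_margin = select_ciw_max_margin(graph, r, behaviors, bvec,
                                         variant),
      eia = select_eia(graph, r, behaviors, bvec, w, variant),
      greedy = select_greedy_kkt(graph, r, behaviors, bvec, w,
                                 spread_runs, variant)
    )
  }
}

table_heuristics <- c("random", "degree_nt", "degree_knap", "degree_t",
                      "degree_resource", "ciw_rank", "ciw_margin", "eia")

#' Reproduce the reference simulation tables
#'
#' Runs the experiment grid behind one of the six reference tables at a
#' configurable scale and returns a tidy results table; every row carries
#' the full configuration (topology, heuristic, variant, distribution,
#' regime, mode, `w`, run count and RNG seed) so it can be reproduced in
#' isolation.
#'
#' * table 2: maximum possible utilization per topology (every node
#'   seeded with its intrinsic knapsack optimum, then diffusion).
#' * tables 3 and 4: the eight seed-selection heuristics per topology;
#'   table 3 reads the `utilization` column, table 4 the
#'   participation/adoption percentages.
#' * table 5: greedy vs the best heuristics on small (`n = 100`, `b = 9`)
#'   instances.
#' * tables 6 and 7: the five behavior-distribution strategies under the
#'   CIW max-margin heuristic; table 6 reads utilization, table 7 the
#'   raw participation/adoption counts.
#'
#' @param table_id which table to reproduce (2-7).
#' @param topologies subset of `c("pa", "sw", "sc")`; a fixed graph read
#'   from `graph_path` is added as topology `"file"` when supplied.
#' @param runs Monte-Carlo runs per configuration (the reference setting
#'   is 5000).
#' @param n synthetic network size (tables 2-4 and 6-7; table 5 always
#'   uses `n = 100`).
#' @param behaviors a [behavior_set()].
#' @param alpha early-adopter fraction, see [seed_budget()].
#' @param w payoff weight.
#' @param mode diffusion mode used for the table runs.
#' @param regime estimation regime, see [estimate_metrics()].
#' @param spread_runs greedy simulation runs per candidate (table 5).
#' @param rng_seed integer seed; each grid row derives its own sub-seed.
#' @param graph_path optional edge-list file for a real-network column.
#' @param out_dir optional directory; when given, the table is written as
#'   `table<ID>.csv` there.
#' @return a `data.frame`, one row per grid cell, with metric means and
#'   standard errors.
#' @export
run_table <- function(table_id, topologies = c("pa", "sw", "sc"),
                      runs = 5000L, n = 500L,
                      behaviors = behavior_set(c(0.2, 0.5, 0.7)),
                      alpha = 0.1, w = 0.5, mode = "reevaluate",
                      regime = "threshold_avg", spread_runs = 1000L,
                      rng_seed = NULL, graph_path = NULL, out_dir = NULL) {
  if (!table_id %in% 2:7) stop_invalid("table_id must be one of 2..7")
  topologies <- match.arg(topologies, c("pa", "sw", "sc"),
                          several.ok = TRUE)
  if (table_id == 5) n <- 100L
  gens <- lapply(topologies, function(tp) graph_generator(tp, n))
  names(gens) <- topologies
  if (!is.null(graph_path)) {
    if (regime == "network_avg") {
      message("fixed input graph: skipping it under the network-average regime")
    } else {
      fixed <- read_edge_list(graph_path)
      gens <- c(gens, list(file = local({
        force(fixed); function() fixed
      })))
    }
  }

  n_of <- vapply(names(gens), function(tp) {
    if (tp == "file") igraph::vcount(gens[[tp]]()) else as.integer(n)
  }, integer(1))
  b_of <- vapply(names(gens), function(tp) {
    if (table_id == 5) 9L else
      seed_budget(alpha, n_of[[tp]], n_behaviors(behaviors))
  }, integer(1))
  heuristics <- switch(as.character(table_id),
    `2` = NA_character_,
    `5` = c("greedy", "ciw_rank", "ciw_margin", "eia"),
    `6` = "ciw_margin", `7` = "ciw_margin",
    table_heuristics)
  distributions <- if (table_id %in% 6:7) {
    c("lowest_only", "inverse_cost", "uniform", "proportional_cost",
      "highest_only")
  } else "uniform"

  grid <- expand.grid(topology = names(gens), heuristic = heuristics,
                      distribution = distributions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    tp <- grid$topology[gi]
    hu <- grid$heuristic[gi]
    ds <- grid$distribution[gi]
    sub_seed <- if (is.null(rng_seed)) NULL else
      (as.integer(rng_seed) + 1000L * gi) %% .Machine$integer.max
    n_tp <- n_of[[tp]]
    est <- if (table_id == 2) {
      max_possible_utilization(gens[[tp]], behaviors, w, runs, regime,
                               rng_seed = sub_seed)
    } else {
      seeder <- make_seeder(hu, behaviors, b_of[[tp]], distribution = ds,
                            variant = "S-T", w = w,
                            spread_runs = spread_runs)
      estimate_metrics(gens[[tp]], behaviors, seeder, w, mode, runs,
                       regime, rng_seed = sub_seed)
    }
    data.frame(table = table_id, topology = tp, heuristic = hu,
               distribution = ds, variant = "S-T", regime = est$regime,
               mode = if (table_id == 2) "reevaluate" else mode, w = w,
               n = n_tp, budget = if (table_id == 2) n_tp else b_of[[tp]],
               runs = est$runs, rng_seed = if (is.null(sub_seed))
                 NA_integer_ else sub_seed,
               participation = est$mean[["participation"]],
               participation_se = est$se[["participation"]],
               participation_pct = 100 * est$mean[["participation"]] / n_tp,
               adoption = est$mean[["adoption"]],
               adoption_se = est$se[["adoption"]],
               adoption_pct = 100 * est$mean[["adoption"]] / n_tp,
               utilization = est$mean[["utilization"]],
               utilization_se = est$se[["utilization"]])
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir,
                                    sprintf("table%d.csv", table_id)),
                     row.names = FALSE)
  }
  out
}
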