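#' Distribute a seed budget over behaviors
#'
#' Splits a total seed budget `b` into per-behavior seed counts. `uniform`
#' splits evenly; `proportional_cost` and `inverse_cost` weight behaviors
#' by cost or reciprocal cost with largest-remainder rounding (remainder
#' ties go to the lower index); `lowest_only` / `highest_only` place the
#' whole budget on the cheapest / most expensive behavior.
#'
#' @param strategy distribution strategy.
#' @param b total seed budget (`b >= 1`).
#' @param behaviors a [behavior_set()].
#' @return a `seed_budget`: an integer vector of per-behavior counts
#'   summing to `b`.
#' @examples
#' b3 <- behavior_set(c(0.2, 0.5, 0.7))
#' distribute_behaviors("uniform", 51, b3)            # 17 17 17
#' distribute_behaviors("proportional_cost", 51, b3)  # 7 18 26
#' @export
distribute_behaviors <- function(strategy = c("lowest_only", "inverse_cost",
                                              "uniform", "proportional_cost",
                                              "highest_only"),
                                 b, behaviors) {
  strategy <- match.arg(strategy)
  if (b < 1) stop_invalid("seed budget must be at least 1")
  b <- as.integer(b)
  k <- n_behaviors(behaviors)
  counts <- switch(strategy,
    lowest_only = c(b, integer(k - 1L)),
    highest_only = c(integer(k - 1L), b),
    uniform = largest_remainder(rep(1, k), b),
    proportional_cost = largest_remainder(behaviors$cost, b),
    inverse_cost = largest_remainder(1 / behaviors$cost, b)
  )
  seed_budget_vector(counts)
}

# largest-remainder apportionment of b items over weights
largest_remainder <- function(wts, b) {
  if (any(!is.finite(wts))) {
    stop_invalid("behavior costs of 0 cannot be weighted by reciprocal cost")
  }
  quota <- b * wts / sum(wts)
  base <- floor(quota + 1e-9)
  spare <- b - sum(base)
  if (spare > 0) {
    ord <- order(quota - base, decreasing = TRUE)  # ties -> lower index
    base[ord[seq_len(spare)]] <- base[ord[seq_len(spare)]] + 1
  }
  as.integer(base)
}

#' @rdname distribute_behaviors
#' @param counts integer vector of per-behavior seed counts.
#' @export
seed_budget_vector <- function(counts) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop_invalid("seed counts must be non-negative")
  structure(counts, class = "seed_budget")
}

# ---------------------------------------------------------------------------
# scan-based selection shared by the random baseline and the naive degree
# heuristic: nodes are consumed in a given order and behaviors assigned by
# one of the tie rules of the reference pseudocode.

assign_by_scan <- function(ord, r, behaviors, b, rule) {
  n <- length(r)
  k <- n_behaviors(behaviors)
  b <- as.integer(b)
  sets <- rep(list(integer(0)), k)
  topup <- numeric(n)
  for (v in ord) {
    if (all(b == 0L)) break
    needed <- which(b > 0L)
    if (rule %in% c("random_nt", "random_t")) {
      j <- if (length(needed) == 1L) needed else
        needed[sample.int(length(needed), 1L)]
      if (rule == "random_nt" && r[v] < behaviors$cost[j] - 1e-12) next
      if (rule == "random_t" && r[v] <= behaviors$cost[j]) {
        topup[v] <- behaviors$cost[j] - r[v]
      }
      sets[[j]] <- c(sets[[j]], v)
      b[j] <- b[j] - 1L
    } else {
      sel <- knapsack_select(needed, behaviors$utility, behaviors, r[v])
      if (length(sel) == 0L && rule == "knapsack_t") {
        j <- needed[which.min(behaviors$cost[needed])]
        topup[v] <- behaviors$cost[j] - r[v]
        sel <- j
      }
      for (j in sel) {
        sets[[j]] <- c(sets[[j]], v)
        b[j] <- b[j] - 1L
      }
    }
  }
  if (any(b > 0L)) {
    stop_invalid("ranking exhausted before the budget was filled for behavior(s) %s",
                 paste(which(b > 0L), collapse = ", "))
  }
  list(sets = sets, topped_up = topup)
}

variant_of_rule <- function(rule) {
  switch(rule, random_nt = "S-NT", random_t = "S-T",
         knapsack = "M-NT", knapsack_t = "M-T")
}

rule_of_variant <- function(variant) {
  switch(variant, `S-NT` = "random_nt", `S-T` = "random_t",
         `M-NT` = "knapsack", `M-T` = "knapsack_t")
}

#' Random seed selection (baseline)
#'
#' Seeds are drawn uniformly at random without replacement and assigned
#' still-needed behaviors; top-up and single/multiple assignment follow
#' the variant.
#'
#' @param graph an `igraph` graph.
#' @param r resource vector (known to the campaign planner).
#' @param budget a `seed_budget` (see [distribute_behaviors()]).
#' @param behaviors a [behavior_set()]; when omitted, behavior costs are
#'   taken to be zero, so no top-up or affordability filtering occurs.
#' @param variant one of `"S-T"`, `"S-NT"`, `"M-T"`, `"M-NT"`.
#' @param rng_seed optional integer seed.
#' @return a [seed_assignment()].
#' @export
select_random <- function(graph, r, budget, behaviors = NULL,
                          variant = "S-T", rng_seed = NULL) {
  n <- igraph::vcount(graph)
  if (sum(budget) > n) stop_invalid("seed budget exceeds the population")
  if (is.null(behaviors)) {
    behaviors <- behavior_set(numeric(length(budget)),
                              numeric(length(budget)))
  }
  with_seed(rng_seed, {
    out <- assign_by_scan(sample.int(n), r, behaviors, budget,
                          rule_of_variant(variant))
    seed_assignment(out$sets, n, variant, out$topped_up)
  })
}

#' Naive degree-based seed selection
#'
#' Nodes are scanned in decreasing degree order (degree ties broken at
#' random) and assigned behaviors by one of three tie rules:
#' `"random_nt"` assigns a uniformly random still-needed behavior only if
#' the node can afford it (otherwise the node is consumed unassigned);
#' `"random_t"` assigns the random behavior unconditionally, topping the
#' resource up to its cost when short; `"knapsack"` pins the node with
#' the utility-maximizing affordable subset of still-needed behaviors.
#'
#' @inheritParams select_random
#' @param behaviors a [behavior_set()].
#' @param tie_rule behavior assignment rule, see Details.
#' @return a [seed_assignment()].
#' @export
select_naive_degree <- function(graph, r, behaviors, budget,
                                tie_rule = c("random_nt", "random_t",
                                             "knapsack"),
                                rng_seed = NULL) {
  tie_rule <- match.arg(tie_rule)
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  with_seed(rng_seed, {
    shuffled <- sample.int(n)
    ord <- shuffled[order(deg[shuffled], decreasing = TRUE)]
    out <- assign_by_scan(ord, r, behaviors, budget, tie_rule)
    seed_assignment(out$sets, n, variant_of_rule(tie_rule), out$topped_up)
  })
}

# ---------------------------------------------------------------------------
# ranked-score selection shared by the degree+resource and CIW-rank
# heuristics: per behavior take the top-b[i] scored nodes, resolve
# cross-behavior collisions at random (with top-up), refill until met.

ranked_select <- function(scores, r, behaviors, budget, variant, n) {
  k <- n_behaviors(behaviors)
  b <- as.integer(budget)
  if (length(b) != k) stop_invalid("budget length must equal the number of behaviors")
  sets <- rep(list(integer(0)), k)
  topup <- numeric(n)
  pool <- seq_len(n)
  nt <- endsWith(variant, "NT")
  single <- startsWith(variant, "S")
  repeat {
    if (all(b == 0L)) break
    claims <- rep(list(integer(0)), k)
    for (i in which(b > 0L)) {
      cand <- pool
      if (nt) cand <- cand[r[cand] >= behaviors$cost[i] - 1e-12]
      if (length(cand) < b[i]) {
        stop_invalid("not enough eligible nodes to fill the budget for behavior %d", i)
      }
      shuffled <- sample_vec(cand)
      ranked <- shuffled[order(scores[shuffled, i], decreasing = TRUE)]
      claims[[i]] <- ranked[seq_len(b[i])]
    }
    chosen <- unique(unlist(claims))
    pool <- setdiff(pool, chosen)
    for (v in sample_vec(chosen)) {
      claiming <- which(vapply(claims, function(ti) v %in% ti, logical(1)))
      claiming <- claiming[b[claiming] > 0L]
      if (length(claiming) == 0L) next
      if (single) {
        j <- if (length(claiming) == 1L) claiming else
          claiming[sample.int(length(claiming), 1L)]
        if (!nt && r[v] + topup[v] <= behaviors$cost[j]) {
          topup[v] <- behaviors$cost[j] - r[v]
        }
        sets[[j]] <- c(sets[[j]], v)
        b[j] <- b[j] - 1L
      } else {
        sel <- knapsack_select(claiming, behaviors$utility, behaviors, r[v])
        if (length(sel) == 0L && !nt) {
          j <- claiming[which.min(behaviors$cost[claiming])]
          topup[v] <- behaviors$cost[j] - r[v]
          sel <- j
        }
        for (j in sel) {
          sets[[j]] <- c(sets[[j]], v)
          b[j] <- b[j] - 1L
        }
      }
    }
  }
  seed_assignment(sets, n, variant, topup)
}

#' Degree-and-resource ranked seed selection
#'
#' Scores each node, per behavior `i`, by `d_i(v)`: the number of
#' neighbors holding enough resource to adopt behavior `i`. The top
#' `b[i]` nodes per behavior are claimed; nodes claimed by several
#' behaviors are assigned one at random (topped up if short), and the
#' shorted behaviors refill from the next-ranked nodes until the budget
#' is met.
#'
#' @inheritParams select_naive_degree
#' @param variant seed variant, see [seed_assignment()].
#' @return a [seed_assignment()].
#' @export
select_degree_resource <- function(graph, r, behaviors, budget,
                                   variant = "S-T", rng_seed = NULL) {
  n <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  k <- n_behaviors(behaviors)
  scores <- vapply(seq_len(k), function(i) {
    rich <- r >= behaviors$cost[i] - 1e-12
    vapply(adj, function(nb) sum(rich[nb]), numeric(1))
  }, numeric(n))
  with_seed(rng_seed,
            ranked_select(scores, r, behaviors, budget, variant, n))
}

#' Constrained Social Influence Weight (CIW)
#'
#' The CIW of node `v` for behavior `i` is
#' `e_i(v) = 1 + sum over resource-sufficient neighbors u of 1/|N(u)|`:
#' a cheap proxy for the one-hop influence `v` can exert, counting only
#' neighbors able to afford the behavior. `excluded` nodes are omitted
#' from the neighbor sum (used by the max-margin variant to discount
#' already-selected seeds).
#'
#' @inheritParams select_naive_degree
#' @param i behavior index.
#' @param excluded integer vector of node indices omitted from the sums.
#' @return numeric vector of `e_i(v)` scores for all nodes.
#' @export
ciw <- function(graph, r, behaviors, i, excluded = integer(0)) {
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  ciw_scores(adj, lengths(adj), r, behaviors$cost[i], excluded)
}

ciw_scores <- function(adj, deg, r, cost_i, excluded = integer(0)) {
  contrib <- ifelse(deg > 0, 1 / deg, 0)
  contrib[r < cost_i - 1e-12] <- 0
  contrib[excluded] <- 0
  1 + vapply(adj, function(nb) sum(contrib[nb]), numeric(1))
}

#' CIW rank-based seed selection
#'
#' Ranks nodes by their Constrained Social Influence Weight [ciw()] per
#' behavior and fills the budget with the same claim/collision/refill
#' skeleton as [select_degree_resource()].
#'
#' @inheritParams select_degree_resource
#' @return a [seed_assignment()].
#' @export
select_ciw_ranked <- function(graph, r, behaviors, budget, variant = "S-T",
                              rng_seed = NULL) {
  n <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  deg <- lengths(adj)
  k <- n_behaviors(behaviors)
  scores <- vapply(seq_len(k), function(i) {
    ciw_scores(adj, deg, r, behaviors$cost[i])
  }, numeric(n))
  with_seed(rng_seed,
            ranked_select(scores, r, behaviors, budget, variant, n))
}

#' CIW max-margin (hill-climbing) seed selection
#'
#' Builds each behavior's seed set greedily on the CIW score: after a
#' node `u` is taken, the score of each remaining neighbor `v` drops by
#' `1/|N(u)|` (the marginal influence `u` already covers), so subsequent
#' picks maximize the marginal CIW gain. Cross-behavior collisions are
#' resolved as in [select_ciw_ranked()].
#'
#' @inheritParams select_degree_resource
#' @return a [seed_assignment()].
#' @export
select_ciw_max_margin <- function(graph, r, behaviors, budget,
                                  variant = "S-T", rng_seed = NULL) {
  n <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  deg <- lengths(adj)
  k <- n_behaviors(behaviors)
  b <- as.integer(budget)
  nt <- endsWith(variant, "NT")
  single <- startsWith(variant, "S")
  sets <- rep(list(integer(0)), k)
  topup <- numeric(n)
  pool <- seq_len(n)
  with_seed(rng_seed, {
    repeat {
      if (all(b == 0L)) break
      claims <- rep(list(integer(0)), k)
      for (i in which(b > 0L)) {
        e <- ciw_scores(adj, deg, r, behaviors$cost[i], excluded = sets[[i]])
        cand <- pool
        if (nt) cand <- cand[r[cand] >= behaviors$cost[i] - 1e-12]
        if (length(cand) < b[i]) {
          stop_invalid("not enough eligible nodes to fill the budget for behavior %d", i)
        }
        ti <- integer(0)
        for (step in seq_len(b[i])) {
          u <- cand[which_max_random(e[cand])]
          ti <- c(ti, u)
          cand <- setdiff(cand, u)
          if (deg[u] > 0) {
            nb <- intersect(adj[[u]], cand)
            e[nb] <- e[nb] - 1 / deg[u]
          }
        }
        claims[[i]] <- ti
      }
      chosen <- unique(unlist(claims))
      pool <- setdiff(pool, chosen)
      for (v in sample_vec(chosen)) {
        claiming <- which(vapply(claims, function(ti) v %in% ti, logical(1)))
        claiming <- claiming[b[claiming] > 0L]
        if (length(claiming) == 0L) next
        if (single) {
          j <- if (length(claiming) == 1L) claiming else
            claiming[sample.int(length(claiming), 1L)]
          if (!nt && r[v] + topup[v] <= behaviors$cost[j]) {
            topup[v] <- behaviors$cost[j] - r[v]
          }
          sets[[j]] <- c(sets[[j]], v)
          b[j] <- b[j] - 1L
        } else {
          sel <- knapsack_select(claiming, behaviors$utility, behaviors, r[v])
          if (length(sel) == 0L && !nt) {
            j <- claiming[which.min(behaviors$cost[claiming])]
            topup[v] <- behaviors$cost[j] - r[v]
            sel <- j
          }
          for (j in sel) {
            sets[[j]] <- c(sets[[j]], v)
            b[j] <- b[j] - 1L
          }
        }
      }
    }
    seed_assignment(sets, n, variant, topup)
  })
}
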