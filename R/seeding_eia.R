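# ---------------------------------------------------------------------------
# Exact one-step adoption probabilities.
#
# Given per-node social signals L (m x k) and resources r, thresholds
# theta_j ~ U(0,1) make behavior j a candidate independently with
# probability q_j = l_j * 1[c_j <= r]; the node then adopts the knapsack
# optimum of the realized candidate set. The adoption probability of each
# behavior is computed exactly by enumerating all 2^k candidate sets.
# Rows are independent, so everything is vectorized across rows.

adoption_probs <- function(L, r, behaviors, w) {
  L <- matrix(L, ncol = n_behaviors(behaviors))
  m <- nrow(L)
  k <- ncol(L)
  nm <- 2L^k
  bit <- 2L^(seq_len(k) - 1L)
  members <- lapply(seq_len(nm) - 1L, function(ms) which(bitwAnd(ms, bit) > 0L))
  mask_costs <- vapply(members, function(j) sum(behaviors$cost[j]), numeric(1))

  aff <- outer(r, behaviors$cost, function(a, b) a >= b - 1e-12)
  q <- L * aff
  pays <- matrix(behaviors$utility * w, m, k, byrow = TRUE) + (1 - w) * L
  pay_mask <- vapply(members, function(j) {
    if (length(j) == 0L) numeric(m) else rowSums(pays[, j, drop = FALSE])
  }, numeric(m))
  pay_mask <- matrix(pay_mask, nrow = m)
  feas <- outer(r, mask_costs, function(a, b) a >= b - 1e-12)

  # preference order over submasks under payoff ties: lower cost, then
  # lexicographically smaller index set; iterating in that order lets a
  # strict payoff improvement be the only reason to switch winners
  lex_key <- vapply(members, function(s) {
    paste(sprintf("%02d", s), collapse = ",")
  }, character(1))
  pref <- order(mask_costs, lex_key)

  submask_cache <- lapply(seq_len(nm) - 1L, function(cs) {
    subs <- which(bitwAnd(seq_len(nm) - 1L, cs) == seq_len(nm) - 1L)
    subs[order(match(subs, pref))]
  })

  P <- matrix(0, m, k)
  for (cs in seq_len(nm) - 1L) {
    csm <- members[[cs + 1L]]
    pw <- rep(1, m)
    for (j in seq_len(k)) {
      pw <- pw * if (j %in% csm) q[, j] else 1 - q[, j]
    }
    live <- pw > 0
    if (!any(live)) next
    best_mask <- integer(m)
    best_pay <- numeric(m)
    for (s in submask_cache[[cs + 1L]]) {
      if (s == 1L) next  # empty set is the initial winner
      upgrade <- live & feas[, s] & (pay_mask[, s] > best_pay + 1e-12)
      best_mask[upgrade] <- s - 1L
      best_pay[upgrade] <- pay_mask[upgrade, s]
    }
    for (j in seq_len(k)) {
      won <- bitwAnd(best_mask, bit[j]) > 0L
      P[, j] <- P[, j] + pw * won
    }
  }
  P
}

#' Expected Immediate Adoption of a behavior
#'
#' Computes `IA_i(S)`, the expected number of nodes adopting behavior `i`
#' exactly one epoch after the seeds in `S` are installed. For each
#' non-seed node adjacent to at least one behavior-`i` seed, the adoption
#' probability is evaluated in closed form: with thresholds uniform on
#' `(0, 1)`, behavior `j` is a candidate independently with probability
#' `l_j(v)` (zero if unaffordable), and the node adopts the knapsack
#' optimum of the realized candidate set; all `2^k` candidate sets are
#' enumerated exactly. The per-node probabilities are summed.
#'
#' @inheritParams select_naive_degree
#' @param seeds a [seed_assignment()].
#' @param i behavior index.
#' @param w payoff weight.
#' @return the expected one-step adoption count `IA_i(S)`.
#' @export
compute_ia <- function(graph, r, behaviors, seeds, i, w = 0.5) {
  n <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  L <- seed_signals(adj, seeds, n_behaviors(behaviors))
  is_seed <- logical(n)
  is_seed[unlist(seeds$sets)] <- TRUE
  vs <- which(!is_seed & L[, i] > 0)
  if (length(vs) == 0L) return(0)
  sum(adoption_probs(L[vs, , drop = FALSE], r[vs], behaviors, w)[, i])
}

# social signals induced by the seed assignment alone
seed_signals <- function(adj, seeds, k) {
  n <- length(adj)
  deg <- lengths(adj)
  L <- matrix(0, n, k)
  for (j in seq_len(k)) {
    ind <- logical(n)
    ind[seeds$sets[[j]]] <- TRUE
    L[, j] <- ifelse(deg > 0,
                     vapply(adj, function(nb) sum(ind[nb]), numeric(1)) /
                       pmax(deg, 1L), 0)
  }
  L
}

#' Incremental Expected Immediate Adoption seed selection
#'
#' Builds the seed set one node at a time. For every behavior still
#' needing seeds, the candidate maximizing the marginal gain in expected
#' one-step adoptions `IA_i` is found (gains are evaluated exactly and
#' only over the candidate's neighborhood, since a new seed perturbs
#' signals only there); the globally best (behavior, node) pair is
#' committed, topped up if short of resource.
#'
#' @inheritParams select_degree_resource
#' @param w payoff weight used in the adoption model.
#' @return a [seed_assignment()].
#' @export
select_eia <- function(graph, r, behaviors, budget, w = 0.5,
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
  is_seed <- logical(n)
  L <- matrix(0, n, k)   # signals from current seeds
  P <- matrix(0, n, k)   # current one-step adoption probabilities

  with_seed(rng_seed, {
    repeat {
      if (all(b == 0L)) break
      best_u <- rep(NA_integer_, k)
      best_gain <- rep(-Inf, k)
      for (i in which(b > 0L)) {
        cands <- if (single) which(!is_seed) else
          setdiff(seq_len(n), sets[[i]])
        if (nt) cands <- cands[r[cands] >= behaviors$cost[i] - 1e-12]
        if (length(cands) == 0L) {
          stop_invalid("no eligible candidates left for behavior %d", i)
        }
        gains <- -P[cands, i]  # the candidate stops being counted itself
        aff <- lapply(cands, function(v) adj[[v]][!is_seed[adj[[v]]]])
        pu <- unlist(aff)
        if (length(pu) > 0L) {
          pc <- rep(seq_along(cands), lengths(aff))
          Lnew <- L[pu, , drop = FALSE]
          Lnew[, i] <- Lnew[, i] + 1 / deg[pu]
          pnew <- adoption_probs(Lnew, r[pu], behaviors, w)[, i]
          dsum <- rowsum(pnew - P[pu, i], pc)
          gains[as.integer(rownames(dsum))] <-
            gains[as.integer(rownames(dsum))] + dsum[, 1]
        }
        pick <- which_max_random(gains)
        best_u[i] <- cands[pick]
        best_gain[i] <- gains[pick]
      }
      i <- which_max_random(ifelse(b > 0L, best_gain, -Inf))
      v <- best_u[i]
      sets[[i]] <- c(sets[[i]], v)
      b[i] <- b[i] - 1L
      is_seed[v] <- TRUE
      if (!nt && r[v] + topup[v] <= behaviors$cost[i]) {
        topup[v] <- behaviors$cost[i] - r[v]
      }
      if (deg[v] > 0) {
        L[adj[[v]], i] <- L[adj[[v]], i] + 1 / deg[v]
        touch <- adj[[v]][!is_seed[adj[[v]]]]
        if (length(touch) > 0L) {
          P[touch, ] <- adoption_probs(L[touch, , drop = FALSE], r[touch],
                                       behaviors, w)
        }
      }
      P[v, ] <- 0
    }
    seed_assignment(sets, n, variant, topup)
  })
}

#' Greedy approximation seed selection (simulation-based)
#'
#' The submodular greedy algorithm for the sticky model: seeds are added
#' one at a time; for each behavior still needing seeds, every remaining
#' candidate's marginal value is scored by the Monte-Carlo estimated
#' total participation of the sticky diffusion with the candidate added
#' (fresh uniform thresholds each simulation run), and the globally best
#' (behavior, node) pair is committed. Under the total-participation
#' objective this greedy achieves at least a `1 - 1/e` (~63%) fraction of
#' the optimal spread.
#'
#' @inheritParams select_eia
#' @param spread_runs Monte-Carlo runs per candidate evaluation.
#' @param spread_fn optional override: a function
#'   `function(seed_assignment) -> numeric` returning the spread estimate
#'   (used in tests with exact enumeration oracles).
#' @return a [seed_assignment()].
#' @export
select_greedy_kkt <- function(graph, r, behaviors, budget, w = 0.5,
                              spread_runs = 1000L, variant = "S-T",
                              rng_seed = NULL, spread_fn = NULL) {
  n <- igraph::vcount(graph)
  adjc <- adj0(graph)
  k <- n_behaviors(behaviors)
  b <- as.integer(budget)
  nt <- endsWith(variant, "NT")
  single <- startsWith(variant, "S")
  sets <- rep(list(integer(0)), k)
  topup <- numeric(n)
  is_seed <- logical(n)

  estimate_spread <- function(sets_try, r_try) {
    if (!is.null(spread_fn)) {
      return(spread_fn(seed_assignment(sets_try, n, "M-T",
                                       pmax(r_try - r, 0))))
    }
    pin <- integer(n)
    for (j in seq_len(k)) {
      pin[sets_try[[j]]] <- bitwOr(pin[sets_try[[j]]],
                                   bitwShiftL(1L, j - 1L))
    }
    mean(.cpp_mc_metrics(adjc, r_try, pin, behaviors$cost,
                         behaviors$utility, w, TRUE, FALSE, 1000L,
                         as.integer(spread_runs))[, 1])
  }

  with_seed(rng_seed, {
    repeat {
      if (all(b == 0L)) break
      best_u <- rep(NA_integer_, k)
      best_s <- rep(-Inf, k)
      for (i in which(b > 0L)) {
        cands <- if (single) which(!is_seed) else
          setdiff(seq_len(n), sets[[i]])
        if (nt) cands <- cands[r[cands] >= behaviors$cost[i] - 1e-12]
        if (length(cands) == 0L) {
          stop_invalid("no eligible candidates left for behavior %d", i)
        }
        svals <- vapply(cands, function(v) {
          sets_try <- sets
          sets_try[[i]] <- c(sets_try[[i]], v)
          r_try <- r + topup
          if (!nt && r_try[v] <= behaviors$cost[i]) {
            r_try[v] <- behaviors$cost[i]
          }
          estimate_spread(sets_try, r_try)
        }, numeric(1))
        pick <- which_max_random(svals)
        best_u[i] <- cands[pick]
        best_s[i] <- svals[pick]
      }
      i <- which_max_random(ifelse(b > 0L, best_s, -Inf))
      v <- best_u[i]
      sets[[i]] <- c(sets[[i]], v)
      b[i] <- b[i] - 1L
      is_seed[v] <- TRUE
      if (!nt && r[v] + topup[v] <= behaviors$cost[i]) {
        topup[v] <- behaviors$cost[i] - r[v]
      }
    }
    seed_assignment(sets, n, variant, topup)
  })
}
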