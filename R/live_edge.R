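#' Live-edge sampling process
#'
#' The live-edge process is an equivalent reformulation of the sticky
#' diffusion dynamics used for validation and submodularity analysis.
#' Before any diffusion, every node `v` draws one incoming edge ("live
#' edge") per behavior it could afford on its own: `kappa(v)` independent
#' draws with replacement, each selecting neighbor `w` with probability
#' `b_{v,w} = 1/|N(v)|` (so the no-edge branch has probability zero for
#' non-isolated nodes). `kappa(v)` is computed from the original `r(v)`.
#'
#' @param graph an `igraph` graph.
#' @param endow an [endowment()] (only `r` is used).
#' @param behaviors a [behavior_set()].
#' @param rng_seed optional integer seed.
#' @return An object of class `live_edge_sample`: a list with one integer
#'   vector per node, of length `kappa(v)`; entry `j` holds the neighbor
#'   index chosen as the live edge for behavior `j` (`NA` for isolated
#'   nodes).
#' @export
sample_live_edges <- function(graph, endow, behaviors, rng_seed = NULL) {
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  kap <- kappa(behaviors, endow$r)
  with_seed(rng_seed, {
    slots <- lapply(seq_along(adj), function(v) {
      if (kap[v] == 0L) return(integer(0))
      nb <- adj[[v]]
      if (length(nb) == 0L) return(rep(NA_integer_, kap[v]))
      nb[sample.int(length(nb), kap[v], replace = TRUE)]
    })
    structure(slots, class = "live_edge_sample")
  })
}

#' Run the live-edge reachability process
#'
#' Deterministic given the sample: diffusion proceeds in sticky epochs,
#' but behavior `j` is a candidate at `v` only when the neighbor chosen as
#' `v`'s live edge for slot `j` adopted `j` in the previous epoch.
#' Adoption is still knapsack-constrained against the residual resource,
#' with payoffs computed from the full-neighborhood social signal, and
#' behaviors stick once adopted.
#'
#' @inheritParams sample_live_edges
#' @param sample a `live_edge_sample` drawn for this graph and endowment.
#' @param seeds a [seed_assignment()].
#' @param w payoff weight.
#' @param max_epochs safety cap (the process terminates within `|V| * k`
#'   epochs).
#' @return as [run_diffusion()]: a list with `result` and `state`.
#' @export
run_live_edge_process <- function(graph, endow, behaviors, sample, seeds,
                                  w = 0.5, max_epochs = NULL) {
  n <- igraph::vcount(graph)
  k <- n_behaviors(behaviors)
  stopifnot(length(sample) == n)
  if (is.null(max_epochs)) max_epochs <- n * k + 1L
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  deg <- lengths(adj)
  r_eff <- r_effective(endow$r, seeds)
  pin <- pinned_masks(seeds)
  adopted <- mask_to_sets(pin, k)
  s <- mask_cost(pin, behaviors)
  if (any(s > r_eff + 1e-9)) {
    stop_invalid("a seed cannot afford its pinned behaviors (missing top-up?)")
  }
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    # adoption indicator matrix from the previous epoch
    has <- matrix(FALSE, n, k)
    for (v in seq_len(n)) has[v, adopted[[v]]] <- TRUE
    nxt <- adopted
    changed <- FALSE
    for (v in seq_len(n)) {
      slots <- sample[[v]]
      if (length(slots) == 0L) next
      residual <- r_eff[v] - s[v]
      cand <- integer(0)
      for (j in seq_along(slots)) {
        if (j %in% adopted[[v]] || is.na(slots[j])) next
        if (has[slots[j], j] && behaviors$cost[j] <= residual + 1e-12) {
          cand <- c(cand, j)
        }
      }
      if (length(cand) == 0L) next
      l <- if (deg[v] > 0) colSums(has[adj[[v]], , drop = FALSE]) / deg[v]
           else numeric(k)
      pays <- w * behaviors$utility + (1 - w) * l
      add <- knapsack_select(cand, pays, behaviors, residual)
      if (length(add) > 0L) {
        nxt[[v]] <- sort(c(adopted[[v]], add))
        s[v] <- s[v] + sum(behaviors$cost[add])
        changed <- TRUE
      }
    }
    adopted <- nxt
    if (!changed || epoch >= max_epochs) break
  }
  active <- sum(lengths(adopted) > 0L)
  state <- structure(list(adopted = adopted, s = s, r = r_eff,
                          pinned = mask_to_sets(pin, k), epoch = epoch),
                     class = "diffusion_state")
  result <- structure(list(participation = active,
                           adoption = sum(lengths(adopted)),
                           utilization = if (sum(r_eff) > 0)
                             sum(s) / sum(r_eff) else NA_real_,
                           epochs_run = epoch, converged = !changed),
                      class = "run_result")
  list(result = result, state = state)
}

#' Participation under a fixed live-edge sample
#'
#' `sigma'_X(S)`: the number of nodes active at the end of the live-edge
#' process for the fixed edge choice `X` encoded by `sample`. As a
#' function of the seed set this quantity is monotone and submodular,
#' which underpins the greedy approximation guarantee.
#'
#' @inheritParams run_live_edge_process
#' @return integer participation count.
#' @export
total_participation_given_sample <- function(graph, endow, behaviors,
                                             sample, seeds, w = 0.5) {
  run_live_edge_process(graph, endow, behaviors, sample, seeds,
                        w = w)$result$participation
}
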