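#' Social signal strength
#'
#' The social signal `l_i(v)` is the summed influence weight exerted on
#' `v` by its neighbors that have adopted behavior `i`; with uniform
#' incoming weights this is the adopting fraction of the neighborhood:
#' `l_i(v) = |{w in N(v): i adopted by w}| / |N(v)|`.
#'
#' @param graph an `igraph` graph.
#' @param state a `diffusion_state` (see [run_diffusion()]) or a list of
#'   per-node adopted behavior index vectors.
#' @param v vertex name or index.
#' @param i behavior index.
#' @return signal strength in `[0, 1]`.
#' @export
social_signal <- function(graph, state, v, i) {
  adopted <- if (inherits(state, "diffusion_state")) state$adopted else state
  nb <- as.integer(igraph::neighbors(graph, v))
  if (length(nb) == 0L) return(0)
  sum(vapply(adopted[nb], function(a) i %in% a, logical(1))) / length(nb)
}

#' Candidate behaviors of a node
#'
#' A behavior `j` is a candidate for adoption at `v` when its social
#' signal has reached the node's private threshold (`l_j(v) >= theta_j(v)`),
#' the node can afford it within the given residual budget
#' (`c_j <= budget`), and the node has not already adopted it.
#'
#' @inheritParams social_signal
#' @param endow an [endowment()].
#' @param behaviors a [behavior_set()].
#' @param budget residual resource available for new adoptions.
#' @return integer vector of candidate behavior indices.
#' @export
candidate_set <- function(graph, state, endow, behaviors, v, budget) {
  stopifnot(budget >= 0)
  adopted <- if (inherits(state, "diffusion_state")) state$adopted else state
  vi <- as.integer(igraph::V(graph)[v])
  k <- n_behaviors(behaviors)
  l <- vapply(seq_len(k), function(j) social_signal(graph, adopted, v, j),
              numeric(1))
  which(l >= endow$theta[vi, ] - 1e-12 &
        behaviors$cost <= budget + 1e-12 &
        !(seq_len(k) %in% adopted[[vi]]))
}

#' Run the multiple-behavior diffusion process
#'
#' Simulates the synchronous-epoch adoption dynamics. Epoch 0 installs
#' each seed's pinned behaviors and charges their cost. In every later
#' epoch all nodes update simultaneously from the previous epoch's state:
#'
#' * `mode = "sticky"` (progressive): each node adds the
#'   payoff-maximizing affordable subset of its current candidates, paid
#'   from its residual resource `r(v) - s(v)`; adopted behaviors are never
#'   dropped and the process stops at the first epoch without change
#'   (guaranteed within `|V| * k` epochs).
#' * `mode = "reevaluate"`: each node reconsiders all behaviors against
#'   its full budget `r(v)`; already-adopted behaviors remain eligible
#'   without re-passing the threshold test, pinned seed behaviors are
#'   always retained, and the adopted set becomes the knapsack optimum of
#'   the eligible set. The process stops at a state fixed point, or at
#'   `max_epochs` with `converged = FALSE` (payoffs move with the signals,
#'   so limit cycles are possible).
#'
#' @param graph an `igraph` graph.
#' @param endow an [endowment()] for this graph.
#' @param behaviors a [behavior_set()].
#' @param seeds a [seed_assignment()] (or `NULL` for no seeds).
#' @param w payoff weight on intrinsic utility, in `[0, 1]`.
#' @param mode `"sticky"` or `"reevaluate"`.
#' @param max_epochs epoch cap for the re-evaluation mode.
#' @return A list with components `result` (class `run_result`:
#'   `participation`, `adoption`, `utilization`, `epochs_run`,
#'   `converged`) and `state` (class `diffusion_state`: per-node adopted
#'   behavior sets `adopted`, spent resource `s`, post-top-up resources
#'   `r`, pinned sets, epoch counter).
#' @examples
#' g <- gen_preferential_attachment(50, rng_seed = 1)
#' b <- behavior_set(c(0.2, 0.5, 0.7))
#' e <- sample_endowments(g, 3, rng_seed = 2)
#' s <- select_random(g, e$r, seed_budget_vector(c(2, 2, 2)), rng_seed = 3)
#' run_diffusion(g, e, b, s, w = 0.5, mode = "sticky")$result
#' @export
run_diffusion <- function(graph, endow, behaviors, seeds = NULL, w = 0.5,
                          mode = c("sticky", "reevaluate"),
                          max_epochs = 1000L) {
  mode <- match.arg(mode)
  n <- igraph::vcount(graph)
  k <- n_behaviors(behaviors)
  stopifnot(length(endow$r) == n, ncol(endow$theta) == k)
  if (is.null(seeds)) seeds <- empty_assignment(k, n)
  if (length(seeds$sets) != k || seeds$n != n) {
    stop_invalid("seed assignment does not match graph/behaviors")
  }
  r_eff <- r_effective(endow$r, seeds)
  pin <- pinned_masks(seeds)
  if (any(mask_cost(pin, behaviors) > r_eff + 1e-9)) {
    stop_invalid("a seed cannot afford its pinned behaviors (missing top-up?)")
  }
  out <- .cpp_run_diffusion(adj0(graph), r_eff, endow$theta, pin,
                            behaviors$cost, behaviors$utility, w,
                            mode == "sticky", FALSE, as.integer(max_epochs))
  build_run(out, r_eff, pin, k)
}

build_run <- function(out, r_eff, pin, k) {
  state <- structure(list(adopted = mask_to_sets(out$adopted, k),
                          s = out$s, r = r_eff,
                          pinned = mask_to_sets(pin, k),
                          epoch = out$epochs),
                     class = "diffusion_state")
  result <- structure(list(participation = out$participation,
                           adoption = out$adoption,
                           utilization = if (sum(r_eff) > 0)
                             sum(out$s) / sum(r_eff) else NA_real_,
                           epochs_run = out$epochs,
                           converged = out$converged),
                      class = "run_result")
  list(result = result, state = state)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "participation %d | adoption %d | utilization %.4f | %d epoch(s)%s\n",
    x$participation, x$adoption, x$utilization, x$epochs_run,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}
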