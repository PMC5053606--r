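#' Resource utilization of a diffusion state
#'
#' The ratio of total spent resource to total available resource,
#' `sum(s(v)) / sum(r(v))`, with post-top-up resources in the
#' denominator.
#'
#' @param state a `diffusion_state` from [run_diffusion()].
#' @param endow optional [endowment()] whose resources override the
#'   state's recorded (post-top-up) resources.
#' @return utilization ratio in `[0, 1]`.
#' @export
resource_utilization <- function(state, endow = NULL) {
  r <- if (!is.null(endow)) endow$r else state$r
  if (sum(r) <= 0) stop_invalid("total resource is zero; utilization undefined")
  sum(state$s) / sum(r)
}

new_metric_estimate <- function(metrics, regime, w, mode) {
  runs <- nrow(metrics)
  means <- colMeans(metrics[, 1:3, drop = FALSE])
  ses <- apply(metrics[, 1:3, drop = FALSE], 2, stats::sd) / sqrt(runs)
  structure(list(
    mean = c(participation = means[[1]], adoption = means[[2]],
             utilization = means[[3]]),
    se = c(participation = ses[[1]], adoption = ses[[2]],
           utilization = ses[[3]]),
    runs = runs, regime = regime, w = w, mode = mode,
    converged_fraction = mean(metrics[, 4])),
    class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo estimate (%s, %d runs, mode %s, w = %.2f):\n",
              x$regime, x$runs, x$mode, x$w))
  for (m in names(x$mean)) {
    cat(sprintf("  %-13s %.4f (se %.4f)\n", m, x$mean[[m]], x$se[[m]]))
  }
  if (x$converged_fraction < 1) {
    cat(sprintf("  [%.1f%% of runs hit the epoch cap]\n",
                100 * (1 - x$converged_fraction)))
  }
  invisible(x)
}

#' Monte-Carlo estimation of the diffusion metrics
#'
#' Estimates expected total participation, total adoption and resource
#' utilization under one of two randomness regimes:
#'
#' * `"threshold_avg"`: one topology (and one resource draw, and one seed
#'   selection) is fixed; the private thresholds are resampled on every
#'   run. Resources are treated as known to the seeding algorithms, so
#'   they are part of the fixed instance.
#' * `"network_avg"`: the threshold vector is fixed (by node index) and
#'   the topology, resources and seed selection are redrawn on every run;
#'   requires a generator closure (see [graph_generator()]), not a fixed
#'   graph.
#'
#' @param graph an `igraph` graph, or a zero-argument generator closure.
#' @param behaviors a [behavior_set()].
#' @param seeder `NULL` (no seeds) or a function
#'   `function(graph, r) -> seed_assignment` (see [make_seeder()]).
#' @param w payoff weight.
#' @param mode diffusion mode, see [run_diffusion()].
#' @param runs number of Monte-Carlo runs.
#' @param regime `"threshold_avg"` or `"network_avg"`.
#' @param rng_seed optional integer seed.
#' @param max_epochs epoch cap per run.
#' @param r optional fixed resource vector for the threshold-average
#'   regime (defaults to a fresh `U(0, 1)` draw).
#' @return a `metric_estimate`: means and standard errors of the three
#'   metrics, plus the run count and regime tag.
#' @export
estimate_metrics <- function(graph, behaviors, seeder = NULL, w = 0.5,
                             mode = c("reevaluate", "sticky"), runs,
                             regime = c("threshold_avg", "network_avg"),
                             rng_seed = NULL, max_epochs = 1000L,
                             r = NULL) {
  mode <- match.arg(mode)
  regime <- match.arg(regime)
  if (runs < 1) stop_invalid("runs must be at least 1")
  if (!is.null(r) && regime == "network_avg") {
    stop_invalid("fixed resources make no sense when topologies are resampled")
  }
  k <- n_behaviors(behaviors)
  with_seed(rng_seed, {
    if (regime == "threshold_avg") {
      g <- if (is.function(graph)) graph() else graph
      n <- igraph::vcount(g)
      if (is.null(r)) r <- stats::runif(n)
      stopifnot(length(r) == n)
      seeds <- if (is.null(seeder)) empty_assignment(k, n) else seeder(g, r)
      metrics <- mc_threshold_runs(g, r, seeds, behaviors, w, mode,
                                   max_epochs, runs)
    } else {
      if (!is.function(graph)) {
        stop_invalid("the network-average regime needs a topology generator, not a fixed graph")
      }
      g1 <- graph()
      n <- igraph::vcount(g1)
      theta <- matrix(stats::runif(n * k), n, k)
      metrics <- t(vapply(seq_len(runs), function(run) {
        g <- graph()
        r <- stats::runif(n)
        seeds <- if (is.null(seeder)) empty_assignment(k, n) else
          seeder(g, r)
        single_run_metrics(g, r, seeds, theta, behaviors, w, mode,
                           max_epochs, FALSE)
      }, numeric(4)))
    }
    new_metric_estimate(metrics, regime, w, mode)
  })
}

mc_threshold_runs <- function(g, r, seeds, behaviors, w, mode, max_epochs,
                              runs, init_intrinsic = FALSE) {
  r_eff <- r_effective(r, seeds)
  pin <- pinned_masks(seeds)
  if (any(mask_cost(pin, behaviors) > r_eff + 1e-9)) {
    stop_invalid("a seed cannot afford its pinned behaviors")
  }
  .cpp_mc_metrics(adj0(g), r_eff, pin, behaviors$cost, behaviors$utility,
                  w, mode == "sticky", init_intrinsic,
                  as.integer(max_epochs), as.integer(runs))
}

single_run_metrics <- function(g, r, seeds, theta, behaviors, w, mode,
                               max_epochs, init_intrinsic) {
  r_eff <- r_effective(r, seeds)
  pin <- pinned_masks(seeds)
  out <- .cpp_run_diffusion(adj0(g), r_eff, theta, pin, behaviors$cost,
                            behaviors$utility, w, mode == "sticky",
                            init_intrinsic, as.integer(max_epochs))
  c(out$participation, out$adoption,
    if (sum(r_eff) > 0) sum(out$s) / sum(r_eff) else NA_real_,
    as.numeric(out$converged))
}

#' Maximum possible resource utilization
#'
#' Estimates the utilization ceiling of a network by seeding every node:
#' at epoch 0 each node adopts its intrinsic-utility knapsack optimum
#' over all behaviors (no thresholds, no signals), then the
#' re-evaluation diffusion runs to equilibrium, during which nodes
#' realign with their neighbors' social signals. The equilibrium
#' utilization upper-bounds what any finite seed budget can achieve; the
#' epoch-0 value (`diffuse = FALSE`) approaches the closed-form bound of
#' [max_utilization()] as the network grows.
#'
#' @inheritParams estimate_metrics
#' @param diffuse if `FALSE`, report the epoch-0 (pre-diffusion)
#'   utilization instead of the equilibrium value.
#' @return a `metric_estimate`.
#' @export
max_possible_utilization <- function(graph, behaviors, w = 0.5, runs,
                                     regime = c("threshold_avg",
                                                "network_avg"),
                                     rng_seed = NULL, max_epochs = 1000L,
                                     diffuse = TRUE) {
  regime <- match.arg(regime)
  if (runs < 1) stop_invalid("runs must be at least 1")
  k <- n_behaviors(behaviors)
  if (!diffuse) max_epochs <- 0L
  with_seed(rng_seed, {
    if (regime == "threshold_avg") {
      g <- if (is.function(graph)) graph() else graph
      r <- stats::runif(igraph::vcount(g))
      metrics <- mc_threshold_runs(g, r, empty_assignment(k,
                                     igraph::vcount(g)),
                                   behaviors, w, "reevaluate", max_epochs,
                                   runs, init_intrinsic = TRUE)
    } else {
      if (!is.function(graph)) {
        stop_invalid("the network-average regime needs a topology generator, not a fixed graph")
      }
      g1 <- graph()
      n <- igraph::vcount(g1)
      theta <- matrix(stats::runif(n * k), n, k)
      metrics <- t(vapply(seq_len(runs), function(run) {
        g <- graph()
        r <- stats::runif(n)
        single_run_metrics(g, r, empty_assignment(k, n), theta, behaviors,
                           w, "reevaluate", max_epochs, TRUE)
      }, numeric(4)))
    }
    new_metric_estimate(metrics, regime, w, "reevaluate")
  })
}
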